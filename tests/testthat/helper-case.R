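# assemble a full synthetic case on disk: planted 17q-style LOH spanning two
# gene intervals plus HRD-dominant catalogues; returns a pipeline_config
build_synthetic_case <- function(dir, seed = 1,
                                 sbs_true = c(SBS1 = 0.2, SBS3 = 0.6,
                                              SBS30 = 0.2),
                                 id_true = c(ID1 = 0.1, ID5 = 0.2, ID6 = 0.7)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seg <- data.frame(start = 2e7, end = 4e7)
  sim <- simulate_paired_sites(segments = seg, seed = seed)
  gvcf <- file.path(dir, "germline.vcf")
  tvcf <- file.path(dir, "tumor.vcf")
  write_paired_vcfs(sim$sites, gvcf, tvcf)
  genes <- capture_regions(c("chr17", "chr17"), c(2.4e7, 3.4e7),
                           c(2.5e7, 3.5e7), c("BRCA1", "RNF43"))
  genes_bed <- file.path(dir, "genes.bed")
  write_bed(genes, genes_bed)

  Ssbs <- random_signature_matrix(3, "SBS96", names(sbs_true), seed = seed + 1)
  Sid <- random_signature_matrix(3, "ID83", names(id_true), seed = seed + 2)
  sbs_cat <- simulate_catalogue(Ssbs, sbs_true, 5000, seed = seed + 3)
  id_cat <- simulate_catalogue(Sid, id_true, 800, seed = seed + 4)
  paths <- list(
    sbs_signatures = file.path(dir, "sbs_signatures.tsv"),
    id_signatures = file.path(dir, "id_signatures.tsv"),
    sbs_catalogue = file.path(dir, "sbs_catalogue.tsv"),
    id_catalogue = file.path(dir, "id_catalogue.tsv"))
  write_signature_matrix(Ssbs, paths$sbs_signatures)
  write_signature_matrix(Sid, paths$id_signatures)
  write_catalogue(sbs_cat, paths$sbs_catalogue)
  write_catalogue(id_cat, paths$id_catalogue)

  pipeline_config(
    sample_id = "synthetic_case",
    inputs = c(list(germline_vcf = gvcf, tumor_vcf_a = tvcf,
                    tumor_vcf_b = tvcf, genes_bed = genes_bed), paths),
    subsets = list(sbs = names(sbs_true), id = names(id_true)),
    seed = seed)
}
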