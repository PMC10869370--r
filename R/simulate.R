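#' Simulate paired germline/tumor allele fractions with planted LOH
#'
#' Places heterozygous germline sites uniformly along a chromosome. Germline
#' alternate reads are Binomial(depth, 0.5). The tumor's expected alternate
#' fraction is 0.5 outside planted segments; inside a copy-neutral LOH
#' segment it is `p * a + (1 - p) * 0.5`, with `p` the cellularity and
#' `a` in \{0, 1\} the retained-allele dosage drawn per segment (which
#' allele was lost). Depths are Poisson around their means (minimum 1).
#' Deterministic given `seed`.
#'
#' @param n_sites Number of heterozygous sites.
#' @param chrom_length Chromosome length in bp.
#' @param segments data.frame with `start`, `end` (1-based, within the
#'   chromosome) of planted copy-neutral LOH segments; may be empty.
#' @param cellularity Tumor purity in (0, 1].
#' @param germline_depth_mean,tumor_depth_mean Mean read depths.
#' @param chrom Chromosome label.
#' @param seed Integer seed.
#' @return list with `sites` (a [paired_sites()] data.frame) and `truth`
#'   (`segments` plus the drawn `lost_allele_dosage` column).
#' @export
simulate_paired_sites <- function(n_sites = 500, chrom_length = 8e7,
                                  segments = data.frame(start = numeric(0),
                                                        end = numeric(0)),
                                  cellularity = 0.8,
                                  germline_depth_mean = 30,
                                  tumor_depth_mean = 60,
                                  chrom = "chr17", seed = 1) {
  stopifnot(cellularity > 0, cellularity <= 1,
            germline_depth_mean > 0, tumor_depth_mean > 0)
  if (nrow(segments) > 0) {
    stopifnot(all(segments$start >= 1), all(segments$end <= chrom_length),
              all(segments$start < segments$end))
  }
  set.seed(seed)
  pos <- sort(sample.int(chrom_length, n_sites))
  a <- if (nrow(segments)) sample(c(0, 1), nrow(segments), replace = TRUE) else
    numeric(0)
  expected <- rep(0.5, n_sites)
  for (j in seq_len(nrow(segments))) {
    inside <- pos >= segments$start[j] & pos <= segments$end[j]
    expected[inside] <- cellularity * a[j] + (1 - cellularity) * 0.5
  }
  gd <- pmax(1L, stats::rpois(n_sites, germline_depth_mean))
  td <- pmax(1L, stats::rpois(n_sites, tumor_depth_mean))
  galt <- stats::rbinom(n_sites, gd, 0.5)
  talt <- stats::rbinom(n_sites, td, expected)
  truth <- segments
  truth$lost_allele_dosage <- a
  list(sites = paired_sites(chrom, pos, galt / gd, gd, talt / td, td),
       truth = truth)
}

#' Write simulated paired sites as a germline/tumor VCF pair
#'
#' Emits two minimal VCF 4.2 files with `GT:AD:DP` fields at the same sites
#' (REF/ALT fixed to A/G), so the scan inputs round-trip through
#' [read_vcf()].
#'
#' @param sites A [paired_sites()] data.frame.
#' @param germline_path,tumor_path Output VCF paths.
#' @return Invisible character vector of the two paths.
#' @export
write_paired_vcfs <- function(sites, germline_path, tumor_path) {
  g <- variant_table(sites$chrom, sites$pos, "A", "G", "PASS",
                     sites$germline_depth,
                     round(sites$germline_vaf * sites$germline_depth))
  t <- variant_table(sites$chrom, sites$pos, "A", "G", "PASS",
                     sites$tumor_depth,
                     round(sites$tumor_vaf * sites$tumor_depth))
  write_vcf(g, germline_path, "GERMLINE")
  write_vcf(t, tumor_path, "TUMOR")
  invisible(c(germline_path, tumor_path))
}

#' Join germline and tumor variant tables into paired sites
#'
#' Germline-heterozygous candidate sites come from the germline calls only;
#' tumor allele fractions are looked up at the same (chrom, pos).
#' Sites absent from the tumor table are dropped.
#'
#' @param germline,tumor Variant data.frames from [read_vcf()].
#' @return A [paired_sites()] data.frame.
#' @export
pair_germline_tumor <- function(germline, tumor) {
  key_g <- paste(germline$chrom, germline$pos)
  key_t <- paste(tumor$chrom, tumor$pos)
  m <- match(key_g, key_t)
  keep <- !is.na(m)
  paired_sites(germline$chrom[keep], germline$pos[keep],
               germline$vaf[keep], germline$depth[keep],
               tumor$vaf[m[keep]], tumor$depth[m[keep]])
}

#' Random synthetic signature matrix
#'
#' Columns are independent flat-Dirichlet draws over the channel alphabet,
#' re-drawn until every pairwise cosine similarity is below `max_cosine`
#' (default 0.8) so that mixture-recovery problems are well conditioned.
#' Deterministic given `seed`.
#'
#' @param n_signatures Number of columns.
#' @param alphabet `"SBS96"` or `"ID83"`.
#' @param names Column names (default `Sig1`, `Sig2`, ...).
#' @param max_cosine Maximum allowed pairwise cosine similarity.
#' @param seed Integer seed.
#' @return A [signature_matrix()].
#' @export
random_signature_matrix <- function(n_signatures, alphabet = c("SBS96", "ID83"),
                                    names = paste0("Sig", seq_len(n_signatures)),
                                    max_cosine = 0.8, seed = 1) {
  alphabet <- match.arg(alphabet)
  n_ch <- if (alphabet == "SBS96") 96L else 83L
  set.seed(seed)
  draw_col <- function() {
    x <- stats::rgamma(n_ch, 1)
    x / sum(x)
  }
  cols <- list()
  attempts <- 0L
  while (length(cols) < n_signatures) {
    cand <- draw_col()
    ok <- all(vapply(cols, function(cc) cosine_similarity(cc, cand) < max_cosine,
                     logical(1)))
    if (ok) cols[[length(cols) + 1L]] <- cand
    attempts <- attempts + 1L
    if (attempts > 1000L * n_signatures) {
      stop("could not draw signatures with pairwise cosine < ", max_cosine)
    }
  }
  mat <- do.call(cbind, cols)
  colnames(mat) <- names
  signature_matrix(mat, alphabet)
}

#' Simulate a mutation catalogue from a known signature mixture
#'
#' Counts are Multinomial(`n_mutations`, `S e_true`). Deterministic given
#' `seed`.
#'
#' @param signatures A [signature_matrix()].
#' @param exposures Named true exposure vector on the simplex; names must be
#'   columns of `signatures`.
#' @param n_mutations Positive total mutation count.
#' @param seed Integer seed.
#' @return A [mutation_catalogue()].
#' @export
simulate_catalogue <- function(signatures, exposures, n_mutations, seed = 1) {
  if (n_mutations <= 0) stop("n_mutations must be positive")
  unknown <- setdiff(names(exposures), colnames(signatures))
  if (length(unknown)) {
    stop("exposure name(s) not in signature matrix: ",
         paste(unknown, collapse = ", "))
  }
  if (abs(sum(exposures) - 1) > 1e-6 || any(exposures < 0)) {
    stop("exposures must be nonnegative and sum to 1")
  }
  p <- as.numeric(unclass(signatures)[, names(exposures), drop = FALSE] %*%
                    exposures)
  set.seed(seed)
  counts <- as.integer(stats::rmultinom(1, n_mutations, p))
  mutation_catalogue(stats::setNames(counts, rownames(signatures)),
                     attr(signatures, "alphabet"))
}

#' Simulate a family table with planted genotypes
#'
#' Emits a data.frame in the family CSV schema with known carrier structure
#' for round-trip testing: `n_dual` members carry both variants (of which
#' `n_dual_crc` get a CRC diagnosis and `n_dual_other_cancer` another
#' malignancy), `n_brca1_only` carry only the first variant, `n_rnf43_only`
#' only the second, and `n_wildtype` neither. Row order is shuffled under the
#' seed.
#'
#' @param n_dual,n_dual_crc,n_dual_other_cancer,n_brca1_only,n_rnf43_only,n_wildtype
#'   Planted group sizes; `n_dual_crc + n_dual_other_cancer <= n_dual`.
#' @param seed Integer seed.
#' @param path Optional CSV output path.
#' @return The family data.frame (written to `path` when given), invisibly
#'   if written.
#' @export
simulate_family <- function(n_dual = 3, n_dual_crc = 2, n_dual_other_cancer = 0,
                            n_brca1_only = 2, n_rnf43_only = 1, n_wildtype = 4,
                            seed = 1, path = NULL) {
  stopifnot(n_dual_crc + n_dual_other_cancer <= n_dual)
  n <- n_dual + n_brca1_only + n_rnf43_only + n_wildtype
  if (n == 0L) {
    df <- utils::read.csv(text = family_csv_header(), stringsAsFactors = FALSE)
  } else {
    set.seed(seed)
    b <- c(rep("carrier", n_dual + n_brca1_only),
           rep("wildtype", n_rnf43_only + n_wildtype))
    r <- c(rep("carrier", n_dual), rep("wildtype", n_brca1_only),
           rep("carrier", n_rnf43_only), rep("wildtype", n_wildtype))
    dx <- c(rep("CRC", n_dual_crc), rep("breast", n_dual_other_cancer),
            rep(NA, n - n_dual_crc - n_dual_other_cancer))
    df <- data.frame(
      person_id = sprintf("S%03d", seq_len(n)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      brca1 = b, rnf43 = r,
      age_last_contact = sample(30:85, n, replace = TRUE),
      record_type = ifelse(is.na(dx), "none", "diagnosis"),
      age = ifelse(is.na(dx), NA, sample(35:75, n, replace = TRUE)),
      tumor_type = dx, location = NA, histology = NA,
      size_min_mm = NA, size_max_mm = NA, count = NA,
      lesion_background = NA, stringsAsFactors = FALSE
    )
    df <- df[sample.int(n), , drop = FALSE]
    rownames(df) <- NULL
  }
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE, na = "")
    return(invisible(df))
  }
  df
}

family_csv_header <- function() {
  paste("person_id,sex,brca1,rnf43,age_last_contact,record_type,age",
        "tumor_type,location,histology,size_min_mm,size_max_mm,count",
        "lesion_background", sep = ",")
}
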