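# lohsig

Tumor characterization for paired germline/tumor sequencing in familial
colorectal cancer (CRC) studies: somatic consensus filtering,
loss-of-heterozygosity (LOH) detection, mutational-signature refitting with a
homologous-recombination-deficiency (HRD) call, and pedigree
carrier/segregation summaries including the WHO-2019 serrated polyposis
syndrome (SPS) criteria.

The package targets the analyst characterizing tumors from families that
segregate candidate tumor-suppressor variants (e.g. *BRCA1* and *RNF43*,
both on chromosome 17q): did the tumor lose the wildtype allele, does its
mutation spectrum show the repair defect the germline variant predicts, and
how do the variants segregate with disease in the family?

## Methods at a glance

**Somatic consensus filter.** Variants reported by two callers (matched on
chrom, pos, ref, alt), PASS in both, with tumor VAF ≥ 0.1 and depth ≥ 50
(inclusive), recomputed from allele depths.

**LOH detection.** At germline-heterozygous sites (germline VAF in
[0.4, 0.6], germline depth ≥ 10, tumor depth ≥ 30), the tumor allele
fraction *f* is purity-corrected for cellularity *p*:

    f_adj = clamp( (f − (1 − p)/2) / p, 0, 1 )

since contaminating normal cells contribute an expected fraction of 1/2 at a
heterozygous site. A site supports LOH when |f_adj − f_germline| ≥ 0.3;
supporting sites are aggregated into regions (≥ 3 supporting sites,
bridging ≤ 1 intervening non-supporting site) and intersected with gene
intervals for per-gene verdicts.

**Signature refitting.** SBS-96 and ID-83 catalogues (PCAWG/COSMIC context
conventions, pyrimidine-strand SNV channels, homopolymer/repeat/microhomology
indel channels) are refit against reference signatures *S* by
simplex-constrained least squares

    min_e || S e − c ||₂   s.t.  e ≥ 0,  Σ e = 1

with *c* the catalogue as proportions, solved as a quadratic program. The
refit is restricted to a configurable CRC-observed subset (15 SBS + 5 ID
signatures by default). A tumor is **HRD-positive** when SBS3 > 10% or
ID6 > 20% of the profile (strict inequalities).

**Pedigree.** Carrier counts (obligate carriers count as carriers), dual
carriers and their cancer/CRC status, and per-member evaluation of the
WHO-2019 SPS criteria (criterion 1: ≥ 5 serrated polyps proximal to the
rectum, all ≥ 5 mm, ≥ 2 of them ≥ 10 mm; criterion 2: > 20 serrated polyps
with ≥ 5 proximal).

A seeded synthetic-data module generates every input with known ground truth
(binomial read sampling around planted copy-neutral LOH segments, multinomial
catalogues from known mixtures, family tables with planted genotypes), so the
whole pipeline is testable offline.

## Worked example

```r
library(lohsig)

# LOH: synthetic chr17 with a planted 20-40 Mb copy-neutral LOH segment
sim  <- simulate_paired_sites(segments = data.frame(start = 2e7, end = 4e7), seed = 1)
scan <- loh_scan(sim$sites)        # cellularity 0.8 default
scan
#> LOH scan: 500 paired sites on 1 chromosome(s)
#>   supporting 112 | no support 258 | uninformative 130
#>   regions: 1
#>     chr17:20168067-39372511 (112 supporting sites)

genes <- capture_regions(c("chr17", "chr17"), c(2.4e7, 3.4e7),
                         c(2.5e7, 3.5e7), c("BRCA1", "RNF43"))
gene_loh_status(scan, genes)
#> BRCA1 RNF43
#> "LOH" "LOH"

# Signatures: refit a catalogue simulated from a known SBS3-dominant mixture
S   <- random_signature_matrix(3, "SBS96", c("SBS1", "SBS3", "SBS30"), seed = 2)
cat <- simulate_catalogue(S, c(SBS1 = 0.2, SBS3 = 0.6, SBS30 = 0.2), 5000, seed = 3)
fit <- fit_signatures(cat, S)
fit
#> Signature refit (SBS96), 5000 mutations, 3 signatures
#>   SBS3      60.1%
#>   SBS30     20.8%
#>   SBS1      19.0%
#>   residual norm 0.01126

hrd_classify(coef(fit), c(ID6 = 0.652, ID5 = 0.305, ID1 = 0.043))$call
#> [1] "HRD_positive"

# Pedigree: packaged family table
fam <- load_family_table(system.file("extdata", "family_table1.csv", package = "lohsig"))
carrier_summary(fam)
#>                brca1_carriers                rnf43_carriers
#>                            10                             8
#>                 dual_carriers dual_carriers_cancer_affected
#>                             7                             6
#>             dual_carriers_crc
#>                             4
```

The recovered region tracks the planted 20–40 Mb segment to within the local
inter-site spacing; the refit exposures recover the simulated 0.2/0.6/0.2
mixture to within sampling noise; and SBS3 at 60% of the profile drives the
HRD call positive. The family counts are 10 and 8 single-variant carriers,
7 dual carriers of whom 6 are cancer-affected and 4 CRC-affected; exactly one
member (`sps_screen(fam)`) meets a WHO-2019 SPS criterion.

`run_case_analysis()` wires the stages together from a YAML configuration
and writes a versioned JSON report plus a one-row summary TSV per tumor; a
thin command-line wrapper ships at `inst/cli/digenic-loh.R`.

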