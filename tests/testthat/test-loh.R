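site1 <- function(gv, gd, tv, td) paired_sites("chr17", 1e6, gv, gd, tv, td)

test_that("depth gates and the heterozygosity window mark sites uninformative", {
  cfg <- loh_config(cellularity = 1, purity_correction = FALSE)
  expect_equal(classify_loh_sites(site1(0.5, 9, 0.95, 100), cfg)$status,
               "UNINFORMATIVE")   # germline depth below 10
  expect_equal(classify_loh_sites(site1(0.5, 10, 0.95, 29), cfg)$status,
               "UNINFORMATIVE")   # tumor depth below 30
  expect_equal(classify_loh_sites(site1(0.39, 30, 0.95, 60), cfg)$status,
               "UNINFORMATIVE")   # outside het window
  # boundaries are inclusive
  expect_equal(classify_loh_sites(site1(0.40, 10, 0.95, 30), cfg)$status,
               "SUPPORTS_LOH")
  expect_equal(classify_loh_sites(site1(0.60, 10, 0.05, 30), cfg)$status,
               "SUPPORTS_LOH")
})

test_that("the 0.3 shift threshold is inclusive with direction by sign", {
  cfg <- loh_config(cellularity = 1, purity_correction = FALSE)
  zero <- classify_loh_sites(site1(0.5, 30, 0.5, 60), cfg)
  expect_equal(zero$status, "NO_SUPPORT")
  expect_true(is.na(zero$direction))
  at <- classify_loh_sites(site1(0.50, 20, 0.80, 40), cfg)
  expect_equal(at$status, "SUPPORTS_LOH")       # shift exactly 0.30
  expect_equal(at$direction, "TOWARD_ALT")
  below <- classify_loh_sites(site1(0.50, 20, 0.7999, 40), cfg)
  expect_equal(below$status, "NO_SUPPORT")
  down <- classify_loh_sites(site1(0.55, 20, 0.20, 40), cfg)
  expect_equal(down$direction, "TOWARD_REF")
})

test_that("purity correction rescales the tumor fraction before thresholding", {
  # (0.90 - 0.2 * 0.5) / 0.8 = 1.0; |1.0 - 0.45| = 0.55 >= 0.3
  call <- classify_loh_sites(site1(0.45, 15, 0.90, 35),
                             loh_config(cellularity = 0.8))
  expect_equal(call$adjusted_tumor_vaf, 1.0)
  expect_equal(call$status, "SUPPORTS_LOH")
  expect_equal(call$direction, "TOWARD_ALT")
  # same observation without correction: shift 0.45 still supports, but the
  # adjusted fraction is the raw one
  raw <- classify_loh_sites(site1(0.45, 15, 0.90, 35),
                            loh_config(purity_correction = FALSE))
  expect_equal(raw$adjusted_tumor_vaf, 0.90)
  expect_equal(adjust_tumor_vaf(0.5, 0.8), 0.5)
  expect_equal(adjust_tumor_vaf(0.9, 1.0), 0.9)
})

test_that("lowering min_shift never removes a supporting site", {
  set.seed(42)
  n <- 300
  sites <- paired_sites("chr1", sort(sample.int(1e7, n)),
                        stats::runif(n), rpois(n, 30),
                        stats::runif(n), rpois(n, 60))
  hi <- classify_loh_sites(sites, loh_config(min_shift = 0.4))
  lo <- classify_loh_sites(sites, loh_config(min_shift = 0.2))
  expect_true(all(which(hi$status == "SUPPORTS_LOH") %in%
                    which(lo$status == "SUPPORTS_LOH")))
})

status_pattern <- function(pat) {
  # pat: character vector of S (support), N (no support), U (uninformative)
  map <- c(S = "SUPPORTS_LOH", N = "NO_SUPPORT", U = "UNINFORMATIVE")
  n <- length(pat)
  data.frame(chrom = "chr1", pos = seq_len(n) * 1000,
             germline_vaf = 0.5, germline_depth = 30,
             tumor_vaf = 0.5, tumor_depth = 60,
             status = unname(map[pat]),
             direction = NA_character_, adjusted_tumor_vaf = 0.5,
             stringsAsFactors = FALSE)
}

test_that("region aggregation bridges small gaps and enforces minimum size", {
  cfg <- loh_config(region_min_sites = 3, region_max_gap_sites = 1)
  r5 <- aggregate_loh_regions(status_pattern(rep("S", 5)), cfg)
  expect_equal(nrow(r5), 1L)
  expect_equal(c(r5$start, r5$end, r5$n_support), c(1000, 5000, 5))
  rg <- aggregate_loh_regions(status_pattern(c("S", "S", "N", "S", "S")), cfg)
  expect_equal(rg$n_support, 4L)
  expect_equal(rg$n_no_support, 1L)
  expect_equal(nrow(aggregate_loh_regions(status_pattern(rep("N", 10)), cfg)), 0L)
  # uninformative sites are transparent
  ru <- aggregate_loh_regions(status_pattern(c("S", "U", "U", "S", "U", "S")), cfg)
  expect_equal(ru$n_support, 3L)
  # a 2-site gap breaks the run
  rb <- aggregate_loh_regions(
    status_pattern(c("S", "S", "S", "N", "N", "S", "S", "S")), cfg)
  expect_equal(nrow(rb), 2L)
  expect_error(aggregate_loh_regions(status_pattern(c("S", "S"))[2:1, ], cfg),
               "sorted")
})

test_that("aggregation agrees with an independent run-enumeration oracle", {
  cfg <- loh_config(region_min_sites = 3, region_max_gap_sites = 1)
  set.seed(11)
  for (rep in 1:40) {
    pat <- sample(c("S", "N", "U"), 40, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    calls <- status_pattern(pat)
    got <- aggregate_loh_regions(calls, cfg)
    want <- oracle_support_groups(calls$status, cfg$region_min_sites,
                                  cfg$region_max_gap_sites)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$start, vapply(want, function(g) calls$pos[g[1]], 0))
      expect_equal(got$end,
                   vapply(want, function(g) calls$pos[g[length(g)]], 0))
      expect_equal(got$n_support, vapply(want, length, 0L))
    }
  }
})

test_that("re-aggregating a region's own sites reproduces the region", {
  cfg <- loh_config()
  sim <- simulate_paired_sites(segments = data.frame(start = 2e7, end = 4e7),
                               seed = 5)
  scan <- loh_scan(sim$sites, cfg)
  expect_gte(nrow(scan$regions), 1L)
  r <- scan$regions[1, ]
  own <- scan$sites[scan$sites$pos >= r$start & scan$sites$pos <= r$end, ]
  again <- aggregate_loh_regions(own, cfg)
  expect_equal(again$start, r$start)
  expect_equal(again$end, r$end)
  expect_equal(again$n_support, r$n_support)
})

test_that("gene verdicts distinguish LOH, NO_LOH and UNINFORMATIVE", {
  sim <- simulate_paired_sites(segments = data.frame(start = 1e7, end = 3e7),
                               seed = 9)
  scan <- loh_scan(sim$sites)
  genes <- capture_regions(rep("chr17", 3), c(1.5e7, 5e7, 7.9999e7),
                           c(1.6e7, 5.1e7, 8e7), c("geneA", "geneB", "geneC"))
  v <- gene_loh_status(scan, genes)
  expect_equal(unname(v["geneA"]), "LOH")
  expect_equal(unname(v["geneB"]), "NO_LOH")
  # geneC sits past the last simulated site often enough; accept either
  # NO_LOH or UNINFORMATIVE there, but an interval with no sites must be
  # UNINFORMATIVE:
  empty_gene <- capture_regions("chr17", 0, 10, "geneZ")
  expect_equal(unname(gene_loh_status(scan, empty_gene)), "UNINFORMATIVE")
  expect_error(gene_loh_status(scan, capture_regions("chr17", 1, 2)), "named")
})

test_that("the allele-fraction plot renders one panel per focus interval", {
  sim <- simulate_paired_sites(segments = data.frame(start = 2e7, end = 4e7),
                               seed = 3)
  scan <- loh_scan(sim$sites)
  png_path <- tempfile(fileext = ".png")
  grDevices::png(png_path, width = 600, height = 600)
  n_panels <- plot(scan)
  grDevices::dev.off()
  expect_equal(n_panels, 1L)
  focus <- capture_regions(c("chr17", "chr17"), c(2e7, 3e7), c(2.5e7, 3.5e7),
                           c("BRCA1", "RNF43"))
  grDevices::png(png_path, width = 600, height = 900)
  n_panels <- plot(scan, focus = focus)
  grDevices::dev.off()
  expect_equal(n_panels, 3L)
  expect_true(file.exists(png_path))
})
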