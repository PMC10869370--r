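fam <- load_family_table(family_fixture_path())

test_that("the packaged family table loads with normalized genotypes", {
  expect_s3_class(fam, "family_table")
  expect_equal(fam[["018"]]$genotype_brca1, "carrier")
  expect_equal(fam[["018"]]$genotype_rnf43, "wildtype")
  expect_equal(fam[["025"]]$genotype_brca1, "obligate_carrier")
  expect_equal(fam[["025"]]$genotype_rnf43, "obligate_carrier")
  expect_equal(fam[["055"]]$genotype_rnf43, "not_tested")
  expect_equal(nrow(fam[["010"]]$polyps), 7L)
  expect_equal(sum(fam[["010"]]$polyps$count), 8L)
})

test_that("an empty table yields an empty family and bad tokens error", {
  p <- tempfile(fileext = ".csv")
  writeLines(lohsig:::family_csv_header(), p)
  expect_length(load_family_table(p), 0L)
  q <- tempfile(fileext = ".csv")
  writeLines(c(lohsig:::family_csv_header(),
               "x1,F,heterozygous,Carrier,50,none,,,,,,,,"), q)
  expect_error(load_family_table(q), "heterozygous")
})

test_that("carrier summary reproduces the published segregation counts", {
  cs <- carrier_summary(fam)
  expect_equal(unname(cs["brca1_carriers"]), 10L)
  expect_equal(unname(cs["rnf43_carriers"]), 8L)
  expect_equal(unname(cs["dual_carriers"]), 7L)
  expect_equal(unname(cs["dual_carriers_cancer_affected"]), 6L)
  expect_equal(unname(cs["dual_carriers_crc"]), 4L)
})

test_that("carrier summary is order-invariant and internally consistent", {
  set.seed(7)
  shuffled <- structure(fam[sample(seq_along(fam))], class = "family_table")
  expect_equal(carrier_summary(shuffled), carrier_summary(fam))
  cs <- carrier_summary(fam)
  expect_lte(cs[["dual_carriers"]],
             min(cs[["brca1_carriers"]], cs[["rnf43_carriers"]]))
  expect_lte(cs[["dual_carriers_crc"]], cs[["dual_carriers_cancer_affected"]])
  expect_lte(cs[["dual_carriers_cancer_affected"]], cs[["dual_carriers"]])
})

test_that("an all-wildtype family counts zero everywhere", {
  p <- tempfile(fileext = ".csv")
  simulate_family(n_dual = 0, n_dual_crc = 0, n_brca1_only = 0,
                  n_rnf43_only = 0, n_wildtype = 5, seed = 1, path = p)
  cs <- carrier_summary(load_family_table(p))
  expect_true(all(cs == 0L))
})

toy_member <- function(polyps) {
  list(person_id = "T", sex = "F", genotype_brca1 = "wildtype",
       genotype_rnf43 = "wildtype", age_last_contact = NA,
       diagnoses = data.frame(), polyps = polyps)
}

polyp_df <- function(location, histology, size, count = 1,
                     lesion_background = FALSE) {
  data.frame(age = 50, location = location, histology = histology,
             size_min_mm = size, size_max_mm = size, count = count,
             lesion_background = lesion_background, stringsAsFactors = FALSE)
}

test_that("WHO-2019 criterion 1 needs 5 large proximal serrated polyps", {
  four <- toy_member(polyp_df("ascending colon", "SSL", 12, count = 4))
  expect_false(sps_who2019(four)$meets_any)
  five <- toy_member(polyp_df("ascending colon", "SSL", 12, count = 5))
  expect_true(sps_who2019(five)$meets_criterion_1)
  # five >= 5 mm but only one >= 10 mm fails
  mixed <- toy_member(rbind(polyp_df("caecum", "hyperplastic", 6, count = 4),
                            polyp_df("caecum", "SSL", 11)))
  expect_false(sps_who2019(mixed)$meets_criterion_1)
  # rectal polyps are not proximal; adenomas never count
  rectal <- toy_member(polyp_df("rectum", "SSL", 12, count = 5))
  expect_false(sps_who2019(rectal)$meets_any)
  adenomas <- toy_member(polyp_df("caecum", "tubular_adenoma", 12, count = 9))
  expect_false(sps_who2019(adenomas)$meets_any)
})

test_that("WHO-2019 criterion 2 counts any-size serrated polyps", {
  m <- toy_member(rbind(polyp_df("transverse colon", "hyperplastic", NA,
                                 count = 15),
                        polyp_df("rectum", "hyperplastic", NA, count = 5)))
  expect_false(sps_who2019(m)$meets_criterion_2)   # exactly 20: not "more than"
  m2 <- toy_member(rbind(polyp_df("transverse colon", "hyperplastic", NA,
                                  count = 16),
                         polyp_df("rectum", "hyperplastic", NA, count = 5)))
  expect_true(sps_who2019(m2)$meets_criterion_2)   # 21 of any size, 16 proximal
  expect_false(sps_who2019(m2)$meets_criterion_1)  # sizes unknown
  few_prox <- toy_member(rbind(polyp_df("sigmoid colon", "hyperplastic", NA,
                                        count = 4),
                               polyp_df("rectum", "hyperplastic", NA,
                                        count = 18)))
  expect_false(sps_who2019(few_prox)$meets_criterion_2)  # < 5 proximal
})

test_that("adding a qualifying polyp never turns a criterion false", {
  base <- polyp_df("ascending colon", "SSL", 12, count = 5)
  r0 <- sps_who2019(toy_member(base))
  r1 <- sps_who2019(toy_member(rbind(base, polyp_df("caecum", "SSL", 15))))
  expect_true(r1$meets_criterion_1 >= r0$meets_criterion_1)
  expect_true(r1$meets_criterion_2 >= r0$meets_criterion_2)
})

test_that("person 010 meets criterion 1 only with the lesion-background SSL", {
  r <- sps_who2019(fam[["010"]])
  expect_true(r$meets_criterion_1)
  expect_false(r$meets_criterion_2)
  without <- sps_who2019(fam[["010"]],
                         sps_config(include_lesion_background_ssl = FALSE))
  expect_false(without$meets_criterion_1)
  # under the midpoint size rule the 6-8 mm polyps still qualify at >= 5 mm
  mid <- sps_who2019(fam[["010"]], sps_config(size_rule = "midpoint"))
  expect_true(mid$meets_criterion_1)
})

test_that("exactly one family member meets any WHO-2019 criterion", {
  scr <- sps_screen(fam)
  expect_equal(scr$person_id[scr$meets_any], "010")
  expect_equal(sum(scr$meets_criterion_1), 1L)
  expect_equal(sum(scr$meets_criterion_2), 0L)
})

test_that("simulated families round-trip planted carrier counts", {
  p <- tempfile(fileext = ".csv")
  simulate_family(n_dual = 3, n_dual_crc = 2, n_dual_other_cancer = 1,
                  n_brca1_only = 2, n_rnf43_only = 1, n_wildtype = 4,
                  seed = 3, path = p)
  cs <- carrier_summary(load_family_table(p))
  expect_equal(unname(cs["dual_carriers"]), 3L)
  expect_equal(unname(cs["brca1_carriers"]), 5L)
  expect_equal(unname(cs["rnf43_carriers"]), 4L)
  expect_equal(unname(cs["dual_carriers_crc"]), 2L)
  expect_equal(unname(cs["dual_carriers_cancer_affected"]), 3L)
  # seeded shuffle: same summary regardless of row order
  df1 <- simulate_family(seed = 4)
  df2 <- df1[rev(seq_len(nrow(df1))), ]
  q1 <- tempfile(fileext = ".csv"); q2 <- tempfile(fileext = ".csv")
  utils::write.csv(df1, q1, row.names = FALSE, na = "")
  utils::write.csv(df2, q2, row.names = FALSE, na = "")
  expect_equal(carrier_summary(load_family_table(q1)),
               carrier_summary(load_family_table(q2)))
  expect_equal(nrow(simulate_family(n_dual = 0, n_dual_crc = 0,
                                    n_brca1_only = 0, n_rnf43_only = 0,
                                    n_wildtype = 0)), 0L)
})
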