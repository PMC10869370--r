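# Fixtures are built in code at test time; nothing binary ships with the
# package.

# write VCF text lines directly (independent of the package's own emitter)
write_vcf_text <- function(records, path, sample = "TUMOR") {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 "FORMAT", sample, sep = "\t"))
  writeLines(c(hdr, records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, filter, ad, gt = "0/1") {
  dp <- sum(as.integer(strsplit(ad, ",")[[1]]))
  paste(chrom, pos, ".", ref, alt, ".", filter, ".", "GT:AD:DP",
        paste(gt, ad, dp, sep = ":"), sep = "\t")
}

# one chromosome per SBS-96 channel, each holding exactly the pyrimidine
# trinucleotide of that channel; returns reference + the 96 variants
sbs96_enumeration_fixture <- function() {
  channels <- sbs96_channels()
  ref_base <- substr(channels, 3, 3)
  alt_base <- substr(channels, 5, 5)
  tri <- paste0(substr(channels, 1, 1), ref_base, substr(channels, 7, 7))
  chroms <- sprintf("s%02d", seq_along(channels))
  reference <- stats::setNames(tri, chroms)
  variants <- variant_table(chroms, 2L, ref_base, alt_base, "PASS", 100L, 30L)
  list(reference = reference, variants = variants, channels = channels)
}

# exhaustive simplex grid search: the independent refit oracle
grid_search_exposures <- function(S, cprop, step = 0.01) {
  k <- ncol(S)
  stopifnot(k %in% c(2L, 3L))
  grid <- seq(0, 1, by = step)
  best <- list(obj = Inf, e = NULL)
  if (k == 2L) {
    for (a in grid) {
      e <- c(a, 1 - a)
      obj <- sum((S %*% e - cprop)^2)
      if (obj < best$obj) best <- list(obj = obj, e = e)
    }
  } else {
    for (a in grid) {
      for (b in grid[grid <= 1 - a + 1e-12]) {
        e <- c(a, b, 1 - a - b)
        obj <- sum((S %*% e - cprop)^2)
        if (obj < best$obj) best <- list(obj = obj, e = e)
      }
    }
  }
  best
}

# independent run-enumeration oracle for LOH region aggregation on one
# chromosome: returns list of supporting-site index vectors
oracle_support_groups <- function(status, min_sites, max_gap) {
  sup <- which(status == "SUPPORTS_LOH")
  if (length(sup) == 0L) return(list())
  informative_ns <- which(status == "NO_SUPPORT")
  groups <- list()
  cur <- sup[1]
  for (s in sup[-1]) {
    between <- sum(informative_ns > cur[length(cur)] & informative_ns < s)
    if (between <= max_gap) {
      cur <- c(cur, s)
    } else {
      groups[[length(groups) + 1L]] <- cur
      cur <- s
    }
  }
  groups[[length(groups) + 1L]] <- cur
  Filter(function(g) length(g) >= min_sites, groups)
}

family_fixture_path <- function() {
  system.file("extdata", "family_table1.csv", package = "lohsig")
}

# planted-LOH recovery check used by unit and acceptance tests: returns TRUE
# when every truth boundary is matched by a region boundary within the gap
# between the informative sites flanking that boundary
segment_recovered <- function(scan, seg) {
  reg <- scan$regions
  reg <- reg[reg$start <= seg$end & reg$end >= seg$start, , drop = FALSE]
  if (nrow(reg) == 0L) return(FALSE)
  inf_pos <- scan$sites$pos[scan$sites$status != "UNINFORMATIVE"]
  flank_gap <- function(boundary) {
    lo <- max(c(-Inf, inf_pos[inf_pos < boundary]))
    hi <- min(c(Inf, inf_pos[inf_pos >= boundary]))
    hi - lo
  }
  start_err <- min(abs(reg$start - seg$start))
  end_err <- min(abs(reg$end - seg$end))
  start_err <= flank_gap(seg$start) && end_err <= flank_gap(seg$end)
}
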