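#' LOH detection configuration
#'
#' Defaults encode the detection rule: germline sites with allele fraction in
#' the inclusive window \[0.4, 0.6\] are treated as heterozygous; sites must
#' have germline depth >= 10 and tumor depth >= 30 to be informative; a
#' purity-adjusted tumor allele fraction shifted by 0.3 or more (inclusive)
#' from the germline fraction supports LOH. Supporting sites are aggregated
#' into regions of at least `region_min_sites` sites tolerating up to
#' `region_max_gap_sites` consecutive non-supporting informative sites.
#'
#' @param het_low,het_high Inclusive germline heterozygosity window.
#' @param min_germline_depth,min_tumor_depth Depth gates (inclusive).
#' @param min_shift Minimum absolute allele-fraction difference (inclusive).
#' @param cellularity Tumor purity in (0, 1]; see [classify_loh_sites()] for
#'   how it enters the adjusted fraction.
#' @param purity_correction Set `FALSE` to threshold the raw tumor fraction.
#' @param region_min_sites Minimum supporting sites per emitted region.
#' @param region_max_gap_sites Maximum consecutive non-supporting informative
#'   sites bridged inside a region.
#' @return An `loh_config` list.
#' @export
loh_config <- function(het_low = 0.4, het_high = 0.6, min_germline_depth = 10,
                       min_tumor_depth = 30, min_shift = 0.3, cellularity = 0.8,
                       purity_correction = TRUE, region_min_sites = 3,
                       region_max_gap_sites = 1) {
  stopifnot(het_low >= 0, het_low < het_high, het_high <= 1,
            min_shift > 0, min_shift <= 1,
            cellularity > 0, cellularity <= 1,
            region_min_sites >= 1, region_max_gap_sites >= 0)
  structure(list(het_low = het_low, het_high = het_high,
                 min_germline_depth = min_germline_depth,
                 min_tumor_depth = min_tumor_depth, min_shift = min_shift,
                 cellularity = cellularity, purity_correction = purity_correction,
                 region_min_sites = region_min_sites,
                 region_max_gap_sites = region_max_gap_sites),
            class = "loh_config")
}

#' Paired germline/tumor sites
#'
#' @param chrom,pos Site coordinates (1-based).
#' @param germline_vaf,germline_depth,tumor_vaf,tumor_depth Observed allele
#'   fractions and read depths in each tissue.
#' @return A data.frame of paired sites.
#' @export
paired_sites <- function(chrom, pos, germline_vaf, germline_depth,
                         tumor_vaf, tumor_depth) {
  stopifnot(all(germline_vaf >= 0 & germline_vaf <= 1),
            all(tumor_vaf >= 0 & tumor_vaf <= 1),
            all(germline_depth >= 0), all(tumor_depth >= 0))
  data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
             germline_vaf = germline_vaf, germline_depth = germline_depth,
             tumor_vaf = tumor_vaf, tumor_depth = tumor_depth,
             stringsAsFactors = FALSE)
}

#' Purity-adjusted tumor allele fraction
#'
#' At a germline-heterozygous site, contaminating normal cells contribute an
#' expected alternate fraction of 0.5, so the tumor-cell fraction is
#' estimated as `(tumor_vaf - (1 - p) * 0.5) / p` with `p` the cellularity,
#' clamped to \[0, 1\]. At `p = 1` this is the raw fraction.
#'
#' @param tumor_vaf Observed tumor allele fraction.
#' @param cellularity Tumor purity in (0, 1].
#' @return Adjusted fraction in \[0, 1\].
#' @export
adjust_tumor_vaf <- function(tumor_vaf, cellularity) {
  pmin(1, pmax(0, (tumor_vaf - (1 - cellularity) * 0.5) / cellularity))
}

#' Classify paired sites for LOH evidence
#'
#' A site is `UNINFORMATIVE` when the germline allele fraction lies outside
#' the heterozygosity window or either depth gate fails. Otherwise it
#' `SUPPORTS_LOH` when the (purity-adjusted) tumor allele fraction differs
#' from the germline fraction by at least `min_shift` in absolute value, with
#' `direction` `"TOWARD_ALT"` for a positive shift and `"TOWARD_REF"` for a
#' negative one; remaining sites are `NO_SUPPORT`.
#'
#' @param sites A [paired_sites()] data.frame.
#' @param cfg An [loh_config()].
#' @return `sites` with added `status`, `direction` and `adjusted_tumor_vaf`
#'   columns.
#' @export
classify_loh_sites <- function(sites, cfg = loh_config()) {
  adj <- if (cfg$purity_correction) {
    adjust_tumor_vaf(sites$tumor_vaf, cfg$cellularity)
  } else {
    sites$tumor_vaf
  }
  informative <- sites$germline_vaf >= cfg$het_low &
    sites$germline_vaf <= cfg$het_high &
    sites$germline_depth >= cfg$min_germline_depth &
    sites$tumor_depth >= cfg$min_tumor_depth
  shift <- adj - sites$germline_vaf
  supports <- informative & abs(shift) >= cfg$min_shift
  sites$status <- ifelse(!informative, "UNINFORMATIVE",
                         ifelse(supports, "SUPPORTS_LOH", "NO_SUPPORT"))
  sites$direction <- ifelse(supports, ifelse(shift > 0, "TOWARD_ALT", "TOWARD_REF"),
                            NA_character_)
  sites$adjusted_tumor_vaf <- adj
  sites
}

#' Aggregate supporting sites into LOH regions
#'
#' Scans classified sites (sorted by chromosome and position) for maximal
#' runs of `SUPPORTS_LOH` sites. `UNINFORMATIVE` sites are transparent;
#' up to `region_max_gap_sites` consecutive `NO_SUPPORT` sites may be
#' bridged. Runs with at least `region_min_sites` supporting sites are
#' emitted, spanning the first to last supporting site.
#'
#' @param calls Output of [classify_loh_sites()], sorted by (chrom, pos).
#' @param cfg An [loh_config()].
#' @return data.frame with columns `chrom`, `start`, `end`, `n_support`,
#'   `n_no_support`.
#' @export
aggregate_loh_regions <- function(calls, cfg = loh_config()) {
  empty <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      n_support = integer(0), n_no_support = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0L) return(empty)
  o <- order(calls$chrom, calls$pos)
  if (!identical(o, seq_len(nrow(calls)))) {
    stop("calls must be sorted by (chrom, pos)")
  }
  out <- list()
  for (chrom in unique(calls$chrom)) {
    cc <- calls[calls$chrom == chrom & calls$status != "UNINFORMATIVE", ,
                drop = FALSE]
    if (nrow(cc) == 0L) next
    run_start <- NA_integer_  # index of first supporting site of current run
    run_last <- NA_integer_   # index of last supporting site
    n_sup <- 0L; n_gap_total <- 0L; gap <- 0L
    flush <- function() {
      if (!is.na(run_start) && n_sup >= cfg$region_min_sites) {
        out[[length(out) + 1L]] <<- data.frame(
          chrom = chrom, start = cc$pos[run_start], end = cc$pos[run_last],
          n_support = n_sup, n_no_support = n_gap_total,
          stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(nrow(cc))) {
      if (cc$status[i] == "SUPPORTS_LOH") {
        if (is.na(run_start)) {
          run_start <- i; n_sup <- 0L; n_gap_total <- 0L
        } else {
          n_gap_total <- n_gap_total + gap
        }
        run_last <- i; n_sup <- n_sup + 1L; gap <- 0L
      } else {
        gap <- gap + 1L
        if (!is.na(run_start) && gap > cfg$region_max_gap_sites) {
          flush()
          run_start <- NA_integer_; gap <- 0L
        }
      }
    }
    flush()
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Scan paired germline/tumor sites for LOH
#'
#' The main fitting-style entry point of the LOH detector: classifies every
#' paired site and aggregates supporting sites into candidate LOH regions.
#'
#' @param sites A [paired_sites()] data.frame (will be sorted by chrom, pos).
#' @param cfg An [loh_config()].
#' @return An object of class `loh_scan` with components `sites` (classified
#'   site calls), `regions` and `config`; supports `print()`, `summary()` and
#'   `plot()`.
#' @export
loh_scan <- function(sites, cfg = loh_config()) {
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  calls <- classify_loh_sites(sites, cfg)
  regions <- aggregate_loh_regions(calls, cfg)
  structure(list(sites = calls, regions = regions, config = cfg),
            class = "loh_scan")
}

#' @export
print.loh_scan <- function(x, ...) {
  tab <- table(factor(x$sites$status,
                      levels = c("SUPPORTS_LOH", "NO_SUPPORT", "UNINFORMATIVE")))
  cat("LOH scan:", nrow(x$sites), "paired sites on",
      length(unique(x$sites$chrom)), "chromosome(s)\n")
  cat(sprintf("  supporting %d | no support %d | uninformative %d\n",
              tab[["SUPPORTS_LOH"]], tab[["NO_SUPPORT"]], tab[["UNINFORMATIVE"]]))
  cat("  regions:", nrow(x$regions), "\n")
  if (nrow(x$regions)) {
    for (i in seq_len(nrow(x$regions))) {
      r <- x$regions[i, ]
      cat(sprintf("    %s:%.0f-%.0f (%d supporting sites)\n",
                  r$chrom, r$start, r$end, r$n_support))
    }
  }
  invisible(x)
}

#' @export
summary.loh_scan <- function(object, ...) {
  print(object)
  cat(sprintf("  cellularity %.2f, min shift %.2f, het window [%.2f, %.2f]\n",
              object$config$cellularity, object$config$min_shift,
              object$config$het_low, object$config$het_high))
  invisible(object)
}

#' Per-gene LOH verdicts
#'
#' A gene is called `LOH` when it overlaps an aggregated LOH region or
#' contains at least one supporting site; `UNINFORMATIVE` when it contains no
#' informative site; otherwise `NO_LOH`.
#'
#' @param scan An [loh_scan()] object.
#' @param genes A [capture_regions()] data.frame with gene `name`s.
#' @return Named character vector of verdicts, one per gene.
#' @export
gene_loh_status <- function(scan, genes) {
  if (any(is.na(genes$name))) stop("gene intervals must be named")
  check_chrom_dialect(scan$sites$chrom, genes$chrom)
  verdict <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    in_gene <- scan$sites$chrom == g$chrom &
      (scan$sites$pos - 1) >= g$start & (scan$sites$pos - 1) < g$end
    informative <- in_gene & scan$sites$status != "UNINFORMATIVE"
    region_hit <- nrow(scan$regions) > 0 && any(
      scan$regions$chrom == g$chrom &
        scan$regions$start <= g$end & scan$regions$end >= g$start + 1)
    if (region_hit || any(in_gene & scan$sites$status == "SUPPORTS_LOH")) {
      verdict[i] <- "LOH"
    } else if (!any(informative)) {
      verdict[i] <- "UNINFORMATIVE"
    } else {
      verdict[i] <- "NO_LOH"
    }
  }
  stats::setNames(verdict, genes$name)
}

#' Allele-fraction plot along a chromosome
#'
#' Plots the tumor allele fraction of germline-heterozygous sites along one
#' chromosome with aggregated LOH regions shaded, plus one zoom panel per
#' focus interval (e.g. individual genes).
#'
#' @param x An [loh_scan()] object.
#' @param chrom Chromosome to plot; defaults to the first in the scan.
#' @param focus Optional [capture_regions()] of zoom intervals.
#' @param adjusted Plot purity-adjusted fractions instead of raw ones.
#' @param ... Ignored.
#' @return The number of panels drawn, invisibly.
#' @export
plot.loh_scan <- function(x, chrom = NULL, focus = NULL, adjusted = FALSE, ...) {
  if (is.null(chrom)) chrom <- x$sites$chrom[1]
  sites <- x$sites[x$sites$chrom == chrom & x$sites$status != "UNINFORMATIVE", ]
  if (nrow(sites) == 0L) stop("no informative sites on ", chrom)
  n_focus <- if (is.null(focus)) 0L else nrow(focus)
  old <- graphics::par(mfrow = c(1L + n_focus, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  yval <- if (adjusted) sites$adjusted_tumor_vaf else sites$tumor_vaf
  draw <- function(xlim, main) {
    graphics::plot(sites$pos, yval, pch = 16, cex = 0.5, ylim = c(0, 1),
                   xlim = xlim, xlab = paste("position on", chrom),
                   ylab = "tumor allele fraction", main = main,
                   col = ifelse(sites$status == "SUPPORTS_LOH", "firebrick",
                                "grey40"))
    reg <- x$regions[x$regions$chrom == chrom, ]
    if (nrow(reg)) {
      graphics::rect(reg$start, -0.04, reg$end, 1.04,
                     col = grDevices::adjustcolor("firebrick", 0.12), border = NA)
    }
    graphics::abline(h = 0.5, lty = 3)
  }
  draw(range(sites$pos), chrom)
  if (n_focus > 0L) {
    for (i in seq_len(n_focus)) {
      f <- focus[i, ]
      draw(c(f$start, f$end),
           if (!is.na(f$name)) f$name else sprintf("%s:%.0f-%.0f", f$chrom,
                                                   f$start, f$end))
    }
  }
  invisible(1L + n_focus)
}
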