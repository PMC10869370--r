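#' Build a table of variant sites
#'
#' The package's working representation of called variants is a plain
#' data.frame with one row per ALT allele and columns `chrom`, `pos` (1-based),
#' `ref`, `alt`, `filter`, `depth`, `alt_depth`, `vaf` and `variant_class`
#' (`"SNV"`, `"insertion"` or `"deletion"`).
#'
#' @param chrom,pos,ref,alt,filter,depth,alt_depth Per-variant fields.
#' @return Validated variant data.frame.
#' @export
variant_table <- function(chrom, pos, ref, alt, filter = "PASS", depth, alt_depth) {
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = toupper(as.character(ref)), alt = toupper(as.character(alt)),
    filter = as.character(filter),
    depth = as.integer(depth), alt_depth = as.integer(alt_depth),
    stringsAsFactors = FALSE
  )
  df$vaf <- ifelse(df$depth > 0, df$alt_depth / df$depth, NA_real_)
  df$variant_class <- variant_class(df$ref, df$alt)
  validate_variant_table(df)
}

variant_class <- function(ref, alt) {
  ifelse(nchar(alt) > nchar(ref), "insertion",
         ifelse(nchar(alt) < nchar(ref), "deletion", "SNV"))
}

validate_variant_table <- function(df) {
  stopifnot(all(df$pos >= 1L, na.rm = TRUE))
  bad <- which(df$alt_depth > df$depth | df$alt_depth < 0L)
  if (length(bad)) {
    stop("alt_depth outside [0, depth] at ", df$chrom[bad[1]], ":", df$pos[bad[1]])
  }
  df
}

empty_variant_table <- function() {
  variant_table(character(0), integer(0), character(0), character(0),
                character(0), integer(0), integer(0))
}

#' Read variant calls from a VCF file
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into the variant table
#' representation. Multi-allelic records are decomposed into one row per ALT
#' allele; depth and VAF are recomputed from the sample's `AD` field
#' (total depth = sum of allele depths), not taken from `DP`.
#'
#' @param path Path to a VCF file.
#' @param sample_name Sample column to read; defaults to the first sample.
#' @return Variant data.frame (see [variant_table()]).
#' @export
read_vcf <- function(path, sample_name = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0L) return(empty_variant_table())
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  names(fix) <- toupper(names(fix))
  gt <- vcf@gt
  samples <- colnames(gt)[-1]
  if (is.null(sample_name)) sample_name <- samples[1]
  if (!sample_name %in% samples) {
    stop("sample '", sample_name, "' not found in ", path,
         " (has: ", paste(samples, collapse = ", "), ")")
  }
  fmt <- strsplit(gt[, "FORMAT"], ":", fixed = TRUE)
  val <- strsplit(gt[, sample_name], ":", fixed = TRUE)
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    ad_i <- match("AD", fmt[[i]])
    if (is.na(ad_i) || ad_i > length(val[[i]])) {
      stop("missing AD field for sample '", sample_name, "' at ",
           fix$CHROM[i], ":", fix$POS[i])
    }
    ad <- suppressWarnings(as.integer(strsplit(val[[i]][ad_i], ",")[[1]]))
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    if (anyNA(ad) || length(ad) != length(alts) + 1L) {
      stop("malformed AD field at ", fix$CHROM[i], ":", fix$POS[i])
    }
    out[[i]] <- data.frame(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      ref = toupper(fix$REF[i]), alt = toupper(alts),
      filter = ifelse(is.na(fix$FILTER[i]), ".", fix$FILTER[i]),
      depth = sum(ad), alt_depth = ad[-1], stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, out)
  df$vaf <- ifelse(df$depth > 0, df$alt_depth / df$depth, NA_real_)
  df$variant_class <- variant_class(df$ref, df$alt)
  validate_variant_table(df)
}

#' Write a variant table to a minimal VCF 4.2 file
#'
#' Emits one bi-allelic record per row with `GT:AD:DP` genotype fields, so
#' that [read_vcf()] round-trips `chrom`, `pos`, `ref`, `alt`, `depth` and
#' `alt_depth`.
#'
#' @param variants Variant data.frame.
#' @param path Output path.
#' @param sample_name Sample column name to write.
#' @param genotypes Optional per-row genotype strings (default `"0/1"`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, sample_name = "SAMPLE", genotypes = NULL) {
  if (is.null(genotypes)) genotypes <- rep("0/1", nrow(variants))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  body <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    ad <- paste(v$depth - v$alt_depth, v$alt_depth, sep = ",")
    body[i] <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", v$filter, ".",
                     "GT:AD:DP", paste(genotypes[i], ad, v$depth, sep = ":"),
                     sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Somatic-variant filter configuration
#'
#' Defaults follow a consensus-calling convention: variants reported by both
#' callers, PASS in both, with tumor VAF of at least 0.1 and total depth of at
#' least 50 reads. Both thresholds are inclusive ("minimum of 0.1" keeps a
#' VAF of exactly 0.1).
#'
#' @param min_vaf Minimum tumor variant allele fraction (inclusive).
#' @param min_depth Minimum total read depth (inclusive).
#' @param require_pass Keep only FILTER == "PASS" records.
#' @param require_both_callers Keep only variants present in both call sets.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_vaf = 0.1, min_depth = 50, require_pass = TRUE,
                          require_both_callers = TRUE) {
  stopifnot(min_vaf >= 0, min_vaf <= 1, min_depth >= 0)
  structure(list(min_vaf = min_vaf, min_depth = min_depth,
                 require_pass = require_pass,
                 require_both_callers = require_both_callers),
            class = "filter_config")
}

variant_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = "\r")

#' Consensus filter over two callers' somatic calls
#'
#' Retains variants reported by both callers (matched on chrom, pos, ref,
#' alt), PASS-filtered in both, with VAF and depth (taken from `calls_a`,
#' recomputed from allele depths at read time) meeting the configured
#' inclusive minimums.
#'
#' @param calls_a,calls_b Variant data.frames from the two callers for the
#'   same tumor sample.
#' @param cfg A [filter_config()].
#' @return Filtered variant data.frame (subset of `calls_a`).
#' @export
consensus_filter <- function(calls_a, calls_b, cfg = filter_config()) {
  keep <- rep(TRUE, nrow(calls_a))
  if (cfg$require_both_callers) {
    b_keys <- variant_key(calls_b)
    if (cfg$require_pass) b_keys <- b_keys[calls_b$filter == "PASS"]
    keep <- keep & variant_key(calls_a) %in% b_keys
  }
  if (cfg$require_pass) keep <- keep & calls_a$filter == "PASS"
  keep <- keep & calls_a$vaf >= cfg$min_vaf & calls_a$depth >= cfg$min_depth
  calls_a[which(keep), , drop = FALSE]
}

#' Capture-region interval set
#'
#' Intervals are stored 0-based half-open (BED convention). [read_bed()]
#' imports a BED file (via \pkg{rtracklayer}) into this representation.
#'
#' @param chrom,start,end Interval coordinates, 0-based half-open.
#' @param name Optional interval labels (e.g. gene names).
#' @return A `capture_regions` data.frame.
#' @export
capture_regions <- function(chrom, start, end, name = NA_character_) {
  stopifnot(all(start < end))
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), name = as.character(name),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  class(df) <- c("capture_regions", "data.frame")
  df
}

#' @rdname capture_regions
#' @param path Path to a BED file.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  capture_regions(as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr), nm)
}

#' Write intervals to a BED file
#'
#' @param regions A [capture_regions()] data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  df <- as.data.frame(regions)
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  cols <- c("chrom", "start", "end")
  if (any(!is.na(df$name))) cols <- c(cols, "name")
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

check_chrom_dialect <- function(calls_chroms, region_chroms) {
  has_chr <- function(x) grepl("^chr", x)
  if (length(calls_chroms) == 0L || length(region_chroms) == 0L) return(invisible())
  if (!any(unique(calls_chroms) %in% unique(region_chroms)) &&
      xor(any(has_chr(calls_chroms)), any(has_chr(region_chroms)))) {
    stop("chromosome naming dialects disagree between variants (",
         calls_chroms[1], ", ...) and regions (", region_chroms[1],
         ", ...); harmonize the 'chr' prefix before filtering")
  }
  invisible()
}

regions_granges <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(start = regions$start + 1L,
                                          end = regions$end))
}

#' Restrict variants to capture regions
#'
#' Keeps variants whose (1-based) position falls inside some interval under
#' the 0-based half-open convention: a variant at 0-based coordinate equal to
#' an interval's `end` is outside it.
#'
#' @param calls Variant data.frame.
#' @param regions A [capture_regions()] set (non-empty).
#' @return Subset of `calls`.
#' @export
restrict_to_capture <- function(calls, regions) {
  stopifnot(nrow(regions) > 0L)
  if (nrow(calls) == 0L) return(calls)
  check_chrom_dialect(calls$chrom, regions$chrom)
  vr <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(start = calls$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(vr, regions_granges(regions))
  calls[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
}
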