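#' SBS-96 channel labels in COSMIC order
#'
#' The 96 single-base-substitution channels, grouped by pyrimidine-strand
#' substitution (C>A, C>G, C>T, T>A, T>C, T>G) and, within each substitution,
#' ordered by 5' then 3' flanking base (A, C, G, T). Labels look like
#' `"A[C>T]G"`.
#'
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases, function(p5, p3) {
      paste0(p5, "[", s, "]", p3)
    })))
  }), use.names = FALSE)
}

#' ID-83 channel labels in COSMIC order
#'
#' The 83 small insertion/deletion channels of the PCAWG/COSMIC convention:
#' 1-bp deletions and insertions split by C/T base and homopolymer length,
#' longer events by repeat-unit count, and deletions at microhomology by
#' homology length. Labels look like `"1:Del:T:5"` or `"3:Del:M:2"`.
#'
#' @return Character vector of length 83.
#' @export
id83_channels <- function() {
  ch <- character(0)
  for (b in c("C", "T")) ch <- c(ch, paste0("1:Del:", b, ":", 0:5))
  for (b in c("C", "T")) ch <- c(ch, paste0("1:Ins:", b, ":", 0:5))
  for (L in 2:5) ch <- c(ch, paste0(L, ":Del:R:", 0:5))
  for (L in 2:5) ch <- c(ch, paste0(L, ":Ins:R:", 0:5))
  for (L in 2:5) ch <- c(ch, paste0(L, ":Del:M:", seq_len(if (L == 5) 5L else L - 1L)))
  ch
}

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", vapply(strsplit(x, NULL), function(s) {
    paste(rev(s), collapse = "")
  }, character(1)))
}

#' Resolve a reference sequence source
#'
#' Accepts a named character vector of chromosome sequences, a
#' [Biostrings::DNAStringSet], or a path to a FASTA file (read with
#' [Biostrings::readDNAStringSet]; names truncated at the first whitespace).
#'
#' @param x Reference source as above.
#' @return Named character vector of upper-case sequences.
#' @export
as_reference_source <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) && is.null(names(x))) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (methods::is(x, "DNAStringSet")) {
    seqs <- as.character(x)
    names(seqs) <- sub("\\s.*$", "", names(x))
    x <- seqs
  }
  if (!is.character(x) || is.null(names(x))) {
    stop("reference source must be a named character vector, DNAStringSet or FASTA path")
  }
  toupper(x)
}

ref_slice <- function(ref, chrom, from, to) {
  if (!chrom %in% names(ref)) stop("chromosome '", chrom, "' absent from reference source")
  n <- nchar(ref[[chrom]])
  from <- max(1L, from)
  to <- min(n, to)
  if (from > to) return("")
  substr(ref[[chrom]], from, to)
}

#' Classify an SNV into its SBS-96 trinucleotide context channel
#'
#' Uses the pyrimidine-strand convention: when the reference base is a purine
#' (A or G) the variant and its context are reverse-complemented before
#' labelling, so e.g. G>A with 5' C and 3' T maps to `"A[C>T]G"`.
#'
#' @param chrom,pos Site coordinates (1-based).
#' @param ref,alt Reference and alternate alleles (single bases).
#' @param reference Reference source accepted by [as_reference_source()].
#' @return One SBS-96 channel label.
#' @export
classify_sbs_context <- function(chrom, pos, ref, alt, reference) {
  rs <- as_reference_source(reference)
  if (nchar(ref) != 1L || nchar(alt) != 1L) stop("classify_sbs_context requires an SNV")
  tri <- ref_slice(rs, chrom, pos - 1L, pos + 1L)
  if (nchar(tri) != 3L) stop("site ", chrom, ":", pos, " lacks flanking context")
  if (substr(tri, 2, 2) != toupper(ref)) {
    stop("reference mismatch at ", chrom, ":", pos, ": reference has ",
         substr(tri, 2, 2), ", variant says ", ref)
  }
  if (toupper(ref) %in% c("A", "G")) {
    tri <- revcomp(tri)
    alt <- revcomp(toupper(alt))
  }
  paste0(substr(tri, 1, 1), "[", substr(tri, 2, 2), ">", toupper(alt), "]",
         substr(tri, 3, 3))
}

# number of tandem copies of `motif` immediately left/right of a reference
# window, within +/- `window` bp
count_tandem <- function(seqchr, left_end, right_start, motif, window = 100L) {
  L <- nchar(motif)
  n_right <- 0L
  i <- right_start
  while (n_right * L < window && substr(seqchr, i, i + L - 1L) == motif &&
         i + L - 1L <= nchar(seqchr)) {
    n_right <- n_right + 1L
    i <- i + L
  }
  n_left <- 0L
  i <- left_end
  while (n_left * L < window && i - L + 1L >= 1L &&
         substr(seqchr, i - L + 1L, i) == motif) {
    n_left <- n_left + 1L
    i <- i - L
  }
  c(left = n_left, right = n_right)
}

longest_common_prefix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  k <- 0L
  while (k < n && substr(a, k + 1L, k + 1L) == substr(b, k + 1L, k + 1L)) k <- k + 1L
  k
}

#' Classify an indel into its ID-83 channel
#'
#' Follows the PCAWG/COSMIC decision tree. Alleles are VCF-style, anchored on
#' a shared leading base (e.g. `ref = "ATT", alt = "A"` deletes `TT`). 1-bp
#' events are split by C/T (A and G counted on the complementary strand) and
#' homopolymer length; longer events by tandem repeat-unit count within a
#' +/- 100 bp window; non-repeat deletions of 2 bp or more are checked for
#' flanking microhomology. Ties between repeat and microhomology
#' classification resolve repeat-first.
#'
#' @inheritParams classify_sbs_context
#' @param ref,alt VCF-style anchored alleles of unequal length.
#' @return One ID-83 channel label.
#' @export
classify_indel_context <- function(chrom, pos, ref, alt, reference) {
  rs <- as_reference_source(reference)
  ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(ref) == nchar(alt)) stop("classify_indel_context requires an indel")
  if (substr(ref, 1, 1) != substr(alt, 1, 1)) {
    stop("alleles at ", chrom, ":", pos, " are not anchored on a shared leading base")
  }
  obs <- ref_slice(rs, chrom, pos, pos + nchar(ref) - 1L)
  if (obs != ref) {
    stop("reference mismatch at ", chrom, ":", pos, ": reference has ", obs,
         ", variant says ", ref)
  }
  seqchr <- rs[[chrom]]
  is_del <- nchar(ref) > nchar(alt)
  motif <- if (is_del) substr(ref, nchar(alt) + 1L, nchar(ref)) else
    substr(alt, nchar(ref) + 1L, nchar(alt))
  L <- nchar(motif)

  if (L == 1L) {
    base <- if (motif %in% c("C", "G")) "C" else "T"
    if (is_del) {
      # homopolymer run containing the deleted base
      tc <- count_tandem(seqchr, pos, pos + 2L, motif)
      run <- 1L + tc[["left"]] + tc[["right"]]
      idx <- min(run, 6L) - 1L
      return(paste0("1:Del:", base, ":", idx))
    }
    # insertion: copies of the base already in the reference around the site
    tc <- count_tandem(seqchr, pos, pos + 1L, motif)
    run <- tc[["left"]] + tc[["right"]]
    return(paste0("1:Ins:", base, ":", min(run, 5L)))
  }

  Lbin <- min(L, 5L)
  if (is_del) {
    del_start <- pos + nchar(alt)              # first deleted base, 1-based
    del_end <- del_start + L - 1L
    tc <- count_tandem(seqchr, del_start - 1L, del_end + 1L, motif)
    n_units <- 1L + tc[["left"]] + tc[["right"]]
    if (n_units >= 2L) {
      return(paste0(Lbin, ":Del:R:", min(n_units, 6L) - 1L))
    }
    right <- ref_slice(rs, chrom, del_end + 1L, del_end + L)
    left <- ref_slice(rs, chrom, del_start - L, del_start - 1L)
    str_rev <- function(x) paste(rev(strsplit(x, NULL)[[1]]), collapse = "")
    hom <- max(longest_common_prefix(motif, right),
               longest_common_prefix(str_rev(motif), str_rev(left)))
    hom <- min(hom, L - 1L)
    if (hom >= 1L) {
      return(paste0(Lbin, ":Del:M:", min(hom, if (Lbin == 5L) 5L else Lbin - 1L)))
    }
    return(paste0(Lbin, ":Del:R:0"))
  }
  tc <- count_tandem(seqchr, pos, pos + 1L, motif)
  n_units <- tc[["left"]] + tc[["right"]]
  paste0(Lbin, ":Ins:R:", min(n_units, 5L))
}
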