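#' Mutation catalogue container
#'
#' A catalogue is a named integer vector of counts over a fixed channel
#' alphabet (`"SBS96"` or `"ID83"`) in COSMIC order, with class
#' `mutation_catalogue`.
#'
#' @param counts Nonnegative counts; either unnamed in COSMIC channel order
#'   or named by channel (missing channels filled with 0).
#' @param alphabet `"SBS96"` or `"ID83"`.
#' @return A `mutation_catalogue` object.
#' @export
mutation_catalogue <- function(counts, alphabet = c("SBS96", "ID83")) {
  alphabet <- match.arg(alphabet)
  channels <- if (alphabet == "SBS96") sbs96_channels() else id83_channels()
  if (is.null(names(counts))) {
    if (length(counts) != length(channels)) {
      stop("unnamed counts must have length ", length(channels), " for ", alphabet)
    }
    counts <- stats::setNames(counts, channels)
  } else {
    unknown <- setdiff(names(counts), channels)
    if (length(unknown)) stop("unknown channels: ", paste(unknown, collapse = ", "))
    full <- stats::setNames(rep(0, length(channels)), channels)
    full[names(counts)] <- counts
    counts <- full
  }
  if (any(counts < 0)) stop("catalogue counts must be nonnegative")
  structure(counts, alphabet = alphabet, class = "mutation_catalogue")
}

#' @export
print.mutation_catalogue <- function(x, ...) {
  cat("Mutation catalogue (", attr(x, "alphabet"), "): ",
      sum(x), " mutations over ", length(x), " channels\n", sep = "")
  top <- sort(unclass(x)[x > 0], decreasing = TRUE)
  if (length(top)) {
    show <- utils::head(top, 5)
    cat("  top channels:",
        paste(sprintf("%s=%d", names(show), as.integer(show)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Build a mutation catalogue from variants
#'
#' Classifies SNVs (for `"SBS96"`) or indels (for `"ID83"`) into context
#' channels against a reference sequence, skipping variants of the other
#' class.
#'
#' @param variants Variant data.frame (see [variant_table()]), already
#'   filtered as desired.
#' @param reference Reference source accepted by [as_reference_source()].
#' @param alphabet `"SBS96"` or `"ID83"`.
#' @return A [mutation_catalogue()] with attribute `n_skipped` counting
#'   variants outside the alphabet's class.
#' @export
build_catalogue <- function(variants, reference, alphabet = c("SBS96", "ID83")) {
  alphabet <- match.arg(alphabet)
  rs <- as_reference_source(reference)
  wanted <- if (alphabet == "SBS96") variants$variant_class == "SNV" else
    variants$variant_class %in% c("insertion", "deletion")
  use <- variants[wanted, , drop = FALSE]
  labels <- character(nrow(use))
  for (i in seq_len(nrow(use))) {
    labels[i] <- if (alphabet == "SBS96") {
      classify_sbs_context(use$chrom[i], use$pos[i], use$ref[i], use$alt[i], rs)
    } else {
      classify_indel_context(use$chrom[i], use$pos[i], use$ref[i], use$alt[i], rs)
    }
  }
  counts <- table(factor(labels, levels = if (alphabet == "SBS96")
    sbs96_channels() else id83_channels()))
  out <- mutation_catalogue(as.integer(counts), alphabet)
  attr(out, "n_skipped") <- sum(!wanted)
  out
}

#' Signature matrix constructor and I/O
#'
#' A signature matrix holds per-signature channel probabilities: one column
#' per signature, rows in COSMIC channel order, each column summing to 1.
#' `read_signature_matrix()` reads a COSMIC-style TSV (first column the
#' channel label, one column per signature); `write_signature_matrix()` is
#' its inverse.
#'
#' @param mat Numeric matrix, channels x signatures.
#' @param alphabet `"SBS96"` or `"ID83"`.
#' @return A validated `signature_matrix` (plain matrix with `alphabet`
#'   attribute).
#' @export
signature_matrix <- function(mat, alphabet = c("SBS96", "ID83")) {
  alphabet <- match.arg(alphabet)
  channels <- if (alphabet == "SBS96") sbs96_channels() else id83_channels()
  if (is.null(rownames(mat))) {
    if (nrow(mat) != length(channels)) {
      stop("matrix must have ", length(channels), " rows for ", alphabet)
    }
    rownames(mat) <- channels
  } else {
    if (!setequal(rownames(mat), channels)) stop("row names must be the ",
                                                 alphabet, " channels")
    mat <- mat[channels, , drop = FALSE]
  }
  if (is.null(colnames(mat))) stop("signature columns must be named")
  if (any(mat < 0)) stop("signature probabilities must be nonnegative")
  csums <- colSums(mat)
  if (any(abs(csums - 1) > 1e-6)) {
    stop("signature columns must sum to 1 (worst deviation ",
         format(max(abs(csums - 1))), ")")
  }
  structure(mat, alphabet = alphabet)
}

#' @rdname signature_matrix
#' @param path TSV path.
#' @export
read_signature_matrix <- function(path, alphabet = c("SBS96", "ID83")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  signature_matrix(mat, match.arg(alphabet))
}

#' @rdname signature_matrix
#' @param sigs A `signature_matrix`.
#' @export
write_signature_matrix <- function(sigs, path) {
  df <- data.frame(Type = rownames(sigs), as.data.frame(unclass(sigs)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a catalogue TSV (channel, count)
#'
#' @param path TSV path.
#' @param alphabet `"SBS96"` or `"ID83"`.
#' @return A [mutation_catalogue()].
#' @export
read_catalogue <- function(path, alphabet = c("SBS96", "ID83")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  mutation_catalogue(stats::setNames(df[[2]], df[[1]]), match.arg(alphabet))
}

#' @rdname read_catalogue
#' @param catalogue A [mutation_catalogue()].
#' @export
write_catalogue <- function(catalogue, path) {
  utils::write.table(
    data.frame(channel = names(catalogue), count = as.integer(catalogue)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default colorectal-cancer signature subset
#'
#' The refit is restricted to signatures previously observed in colorectal
#' tumors: 15 single-base-substitution and 5 indel signatures. The exact
#' list is a configurable analysis choice; this default covers the
#' common CRC processes (clock-like SBS1/SBS5, HRD-associated SBS3 and ID6,
#' APOBEC SBS2/13, POLE SBS10a/b, MMR SBS15/44, SBS17a/b, SBS18, SBS28,
#' SBS30, SBS40 and ID1/2/4/5/6).
#'
#' @return list with components `sbs` and `id` (character vectors).
#' @export
default_crc_signatures <- function() {
  list(sbs = c("SBS1", "SBS2", "SBS3", "SBS5", "SBS10a", "SBS10b", "SBS13",
               "SBS15", "SBS17a", "SBS17b", "SBS18", "SBS28", "SBS30",
               "SBS40", "SBS44"),
       id = c("ID1", "ID2", "ID4", "ID5", "ID6"))
}

# min ||S e - c||^2 s.t. e >= 0, sum(e) = 1, via quadprog; c is the
# proportion-normalized catalogue
solve_simplex_lsq <- function(S, cprop) {
  k <- ncol(S)
  Dmat <- crossprod(S)
  dvec <- as.numeric(crossprod(S, cprop))
  Amat <- cbind(rep(1, k), diag(k))
  bvec <- c(1, rep(0, k))
  sol <- NULL
  for (ridge in c(0, 1e-10, 1e-8, 1e-6)) {
    sol <- tryCatch(
      quadprog::solve.QP(Dmat + diag(ridge, k), dvec, Amat, bvec, meq = 1),
      error = function(e) NULL)
    if (!is.null(sol)) break
  }
  if (is.null(sol)) stop("signature refit QP could not be solved")
  e <- pmax(sol$solution, 0)
  e / sum(e)
}

#' Refit a mutation catalogue against reference signatures
#'
#' Estimates the nonnegative mixture of reference signatures that best
#' reconstructs an observed catalogue: with `c` the catalogue normalized to
#' proportions and `S` the selected signature columns, solves
#' `min ||S e - c||_2` subject to `e >= 0` and `sum(e) = 1` (a quadratic
#' program, solved deterministically). SBS and ID catalogues are refit
#' independently on their own alphabets.
#'
#' @param catalogue A [mutation_catalogue()] with positive total count.
#' @param signatures A [signature_matrix()] on the same alphabet.
#' @param subset Signature names to refit over (default: all columns).
#' @return An object of class `signature_fit` with methods `coef()`
#'   (exposure proportions), `fitted()`, `residuals()`, `predict()`,
#'   `print()`, `summary()` and `plot()`.
#' @export
fit_signatures <- function(catalogue, signatures, subset = NULL) {
  stopifnot(inherits(catalogue, "mutation_catalogue"))
  if (attr(catalogue, "alphabet") != attr(signatures, "alphabet")) {
    stop("catalogue and signature matrix use different alphabets")
  }
  total <- sum(catalogue)
  if (total <= 0) stop("catalogue is empty; cannot refit")
  if (is.null(subset)) subset <- colnames(signatures)
  unknown <- setdiff(subset, colnames(signatures))
  if (length(unknown)) {
    stop("unknown signature name(s): ", paste(unknown, collapse = ", "))
  }
  S <- unclass(signatures)[, subset, drop = FALSE]
  cprop <- as.numeric(catalogue) / total
  e <- solve_simplex_lsq(S, cprop)
  names(e) <- subset
  fitted_prop <- as.numeric(S %*% e)
  structure(list(
    exposures = e,
    residual_norm = sqrt(sum((fitted_prop - cprop)^2)),
    catalogue = catalogue,
    catalogue_prop = stats::setNames(cprop, names(catalogue)),
    fitted_prop = stats::setNames(fitted_prop, names(catalogue)),
    signatures = S,
    alphabet = attr(catalogue, "alphabet"),
    n_mutations = total
  ), class = "signature_fit")
}

#' @export
coef.signature_fit <- function(object, ...) object$exposures

#' @export
fitted.signature_fit <- function(object, ...) object$fitted_prop

#' @export
residuals.signature_fit <- function(object, ...) {
  object$catalogue_prop - object$fitted_prop
}

#' Predict expected channel counts from a signature fit
#'
#' @param object A `signature_fit`.
#' @param n_mutations Total mutation count to scale to (default: the fitted
#'   catalogue's total).
#' @param ... Ignored.
#' @return Named numeric vector of expected per-channel counts.
#' @export
predict.signature_fit <- function(object, n_mutations = object$n_mutations, ...) {
  object$fitted_prop * n_mutations
}

#' @export
print.signature_fit <- function(x, digits = 3, hide_below = 1e-4, ...) {
  cat("Signature refit (", x$alphabet, "), ", x$n_mutations, " mutations, ",
      length(x$exposures), " signatures\n", sep = "")
  e <- x$exposures
  e[e < hide_below] <- 0   # machine values retained in x$exposures
  e <- sort(e[e > 0], decreasing = TRUE)
  for (nm in names(e)) cat(sprintf("  %-8s %5.1f%%\n", nm, 100 * e[[nm]]))
  cat(sprintf("  residual norm %.4g\n", x$residual_norm))
  invisible(x)
}

#' @export
summary.signature_fit <- function(object, ...) {
  print(object, ...)
  cat(sprintf("  reconstruction cosine %.4f\n",
              cosine_similarity(object$catalogue_prop, object$fitted_prop)))
  invisible(object)
}

cosine_similarity <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' HRD classification rule configuration
#'
#' @param sbs3_threshold Exposure proportion above which SBS3 indicates HRD
#'   (strict inequality; default 0.10).
#' @param id6_threshold Same for ID6 (default 0.20).
#' @return An `hrd_rule` list.
#' @export
hrd_rule <- function(sbs3_threshold = 0.10, id6_threshold = 0.20) {
  stopifnot(sbs3_threshold >= 0, sbs3_threshold <= 1,
            id6_threshold >= 0, id6_threshold <= 1)
  structure(list(sbs3_threshold = sbs3_threshold, id6_threshold = id6_threshold),
            class = "hrd_rule")
}

#' Classify homologous recombination deficiency from signature exposures
#'
#' A tumor is HRD-positive when SBS3 exceeds 10% or ID6 exceeds 20% of the
#' refit signature profile (strict inequalities: exposures exactly at the
#' threshold are negative).
#'
#' @param sbs_exposures Named exposure vector containing `SBS3` (a
#'   `signature_fit` is also accepted).
#' @param id_exposures Named exposure vector containing `ID6` (or a
#'   `signature_fit`).
#' @param rule An [hrd_rule()].
#' @return list with `call` (`"HRD_positive"` or `"HRD_negative"`), logical
#'   `sbs3_fired` / `id6_fired`, the tested proportions and `reasons`.
#' @export
hrd_classify <- function(sbs_exposures, id_exposures, rule = hrd_rule()) {
  if (inherits(sbs_exposures, "signature_fit")) sbs_exposures <- coef(sbs_exposures)
  if (inherits(id_exposures, "signature_fit")) id_exposures <- coef(id_exposures)
  if (!"SBS3" %in% names(sbs_exposures)) {
    stop("SBS3 absent from the SBS exposure vector; the refit subset must include it")
  }
  if (!"ID6" %in% names(id_exposures)) {
    stop("ID6 absent from the ID exposure vector; the refit subset must include it")
  }
  sbs3 <- unname(sbs_exposures[["SBS3"]])
  id6 <- unname(id_exposures[["ID6"]])
  sbs3_fired <- sbs3 > rule$sbs3_threshold
  id6_fired <- id6 > rule$id6_threshold
  reasons <- c(
    if (sbs3_fired) sprintf("SBS3 = %.1f%% > %.0f%%", 100 * sbs3,
                            100 * rule$sbs3_threshold),
    if (id6_fired) sprintf("ID6 = %.1f%% > %.0f%%", 100 * id6,
                           100 * rule$id6_threshold))
  list(call = if (sbs3_fired || id6_fired) "HRD_positive" else "HRD_negative",
       sbs3_fired = sbs3_fired, id6_fired = id6_fired,
       sbs3 = sbs3, id6 = id6,
       reasons = if (length(reasons)) reasons else "no rule fired")
}

#' Catalogue context-profile bar plot
#'
#' Draws the catalogue as a bar plot over channels in COSMIC order, grouped
#' by substitution type (SBS-96) or indel class (ID-83), with an optional
#' second panel showing a reference signature for visual comparison,
#' annotated with their cosine similarity.
#'
#' @param catalogue A [mutation_catalogue()].
#' @param reference_signature Optional single-signature probability vector on
#'   the same alphabet (e.g. one column of a [signature_matrix()]).
#' @param main Title.
#' @return Cosine similarity to the reference signature (or `NA`), invisibly.
#' @export
plot_catalogue <- function(catalogue, reference_signature = NULL,
                           main = "mutation catalogue") {
  alphabet <- attr(catalogue, "alphabet")
  group <- if (alphabet == "SBS96") {
    sub("^.\\[(.*)\\].$", "\\1", names(catalogue))
  } else {
    sub("^([0-9]+:(Del|Ins):[CTRM]):.*$", "\\1", names(catalogue))
  }
  cols <- grDevices::hcl.colors(length(unique(group)), "Dark 3")[factor(
    group, levels = unique(group))]
  panels <- 1L + !is.null(reference_signature)
  old <- graphics::par(mfrow = c(panels, 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  draw <- function(y, ttl) {
    bp <- graphics::barplot(as.numeric(y), col = cols, border = NA, main = ttl,
                            ylab = if (sum(y) > 1.5) "count" else "proportion")
    breaks <- which(diff(as.integer(factor(group, levels = unique(group)))) != 0)
    graphics::abline(v = (bp[breaks] + bp[breaks + 1]) / 2, col = "grey80")
  }
  draw(catalogue, main)
  sim <- NA_real_
  if (!is.null(reference_signature)) {
    sim <- cosine_similarity(as.numeric(catalogue) / max(1, sum(catalogue)),
                             as.numeric(reference_signature))
    draw(reference_signature,
         sprintf("reference signature (cosine %.3f)", sim))
  }
  invisible(sim)
}
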