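PIPELINE_KEYS <- c("sample_id", "inputs", "filter", "loh", "hrd", "subsets",
                   "out_dir", "seed")
INPUT_KEYS <- c("tumor_vcf_a", "tumor_vcf_b", "tumor_sample", "germline_vcf",
                "capture_bed", "genes_bed", "reference_fasta",
                "sbs_catalogue", "id_catalogue", "sbs_signatures",
                "id_signatures", "sbs_exposures", "id_exposures")

#' Pipeline configuration
#'
#' Assembles and validates the nested configuration consumed by
#' [run_case_analysis()]. Unknown keys are rejected.
#' `load_pipeline_config()` and `write_pipeline_config()` round-trip the
#' configuration through YAML.
#'
#' @param sample_id Tumor/sample label.
#' @param inputs Named list of input paths (any of `tumor_vcf_a`,
#'   `tumor_vcf_b`, `tumor_sample`, `germline_vcf`, `capture_bed`,
#'   `genes_bed`, `reference_fasta`, `sbs_catalogue`, `id_catalogue`,
#'   `sbs_signatures`, `id_signatures`, `sbs_exposures`, `id_exposures`).
#'   Stages whose inputs are absent are skipped.
#' @param filter,loh,hrd Named lists of overrides for [filter_config()],
#'   [loh_config()] and [hrd_rule()].
#' @param subsets list with `sbs` and `id` signature-name vectors for the
#'   refit (default [default_crc_signatures()]).
#' @param out_dir Output directory for reports (`NULL` = do not write).
#' @param seed Integer recorded in the report.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sample_id = "sample", inputs = list(),
                            filter = list(), loh = list(), hrd = list(),
                            subsets = default_crc_signatures(),
                            out_dir = NULL, seed = 1) {
  unknown <- setdiff(names(inputs), INPUT_KEYS)
  if (length(unknown)) stop("unknown input key(s): ", paste(unknown, collapse = ", "))
  structure(list(sample_id = sample_id, inputs = inputs,
                 filter = do.call(filter_config, filter),
                 loh = do.call(loh_config, loh),
                 hrd = do.call(hrd_rule, hrd),
                 subsets = subsets, out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML path.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), PIPELINE_KEYS)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  out <- list(sample_id = cfg$sample_id, inputs = cfg$inputs,
              filter = unclass(cfg$filter), loh = unclass(cfg$loh),
              hrd = unclass(cfg$hrd), subsets = cfg$subsets,
              out_dir = cfg$out_dir, seed = cfg$seed)
  yaml::write_yaml(out[!vapply(out, is.null, logical(1))], path)
  invisible(path)
}

#' Write/read exposure vectors as JSON
#'
#' @param exposures Named exposure vector or a `signature_fit`.
#' @param path JSON path.
#' @return `path` (write) or named numeric vector (read).
#' @export
write_exposures <- function(exposures, path) {
  if (inherits(exposures, "signature_fit")) exposures <- coef(exposures)
  jsonlite::write_json(as.list(exposures), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_exposures
#' @export
read_exposures <- function(path) {
  unlist(jsonlite::read_json(path, simplifyVector = TRUE))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the end-to-end case analysis
#'
#' Wires the stages together for one tumor: consensus-filter the two
#' callers' somatic calls and restrict them to the capture region; scan
#' paired germline/tumor sites for LOH and call per-gene verdicts; build or
#' load SBS/ID catalogues, refit signature exposures and apply the HRD rule.
#' Stages whose inputs are not configured are skipped. When `out_dir` is
#' set, a versioned JSON report and a one-row summary TSV are written.
#'
#' @param config A [pipeline_config()], or a path to its YAML form.
#' @return A `case_report` list (invisibly when `out_dir` is set).
#' @export
run_case_analysis <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  inp <- config$inputs
  report <- list(schema_version = "1.0", sample_id = config$sample_id,
                 seed = config$seed)

  if (!is.null(inp$tumor_vcf_a) && !is.null(inp$tumor_vcf_b)) {
    report$variants <- with_stage("variants", {
      a <- read_vcf(inp$tumor_vcf_a, inp$tumor_sample)
      b <- read_vcf(inp$tumor_vcf_b, inp$tumor_sample)
      kept <- consensus_filter(a, b, config$filter)
      n_consensus <- nrow(kept)
      if (!is.null(inp$capture_bed)) {
        kept <- restrict_to_capture(kept, read_bed(inp$capture_bed))
      }
      list(n_caller_a = nrow(a), n_caller_b = nrow(b),
           n_consensus = n_consensus, n_retained = nrow(kept),
           retained = kept)
    })
  }

  if (!is.null(inp$germline_vcf) && !is.null(inp$tumor_vcf_a)) {
    report$loh <- with_stage("loh", {
      germ <- read_vcf(inp$germline_vcf)
      tum <- read_vcf(inp$tumor_vcf_a, inp$tumor_sample)
      scan <- loh_scan(pair_germline_tumor(germ, tum), config$loh)
      genes <- if (!is.null(inp$genes_bed)) {
        as.list(gene_loh_status(scan, read_bed(inp$genes_bed)))
      }
      list(n_sites = nrow(scan$sites),
           n_informative = sum(scan$sites$status != "UNINFORMATIVE"),
           n_supporting = sum(scan$sites$status == "SUPPORTS_LOH"),
           regions = scan$regions, genes = genes, scan = scan)
    })
  }

  sbs_expo <- id_expo <- NULL
  report$signatures <- with_stage("signatures", {
    sigres <- list()
    refit_one <- function(cat_path, sig_path, alphabet, subset) {
      catalogue <- read_catalogue(cat_path, alphabet)
      sigs <- read_signature_matrix(sig_path, alphabet)
      fit_signatures(catalogue, sigs, intersect(subset, colnames(sigs)))
    }
    if (!is.null(inp$sbs_exposures)) {
      sbs_expo <- read_exposures(inp$sbs_exposures)
      sigres$sbs <- list(exposures = as.list(sbs_expo), source = "provided")
    } else if (!is.null(inp$sbs_catalogue) && !is.null(inp$sbs_signatures)) {
      fit <- refit_one(inp$sbs_catalogue, inp$sbs_signatures, "SBS96",
                       config$subsets$sbs)
      sbs_expo <- coef(fit)
      sigres$sbs <- list(exposures = as.list(sbs_expo),
                         residual_norm = fit$residual_norm,
                         n_mutations = fit$n_mutations, source = "refit")
    }
    if (!is.null(inp$id_exposures)) {
      id_expo <- read_exposures(inp$id_exposures)
      sigres$id <- list(exposures = as.list(id_expo), source = "provided")
    } else if (!is.null(inp$id_catalogue) && !is.null(inp$id_signatures)) {
      fit <- refit_one(inp$id_catalogue, inp$id_signatures, "ID83",
                       config$subsets$id)
      id_expo <- coef(fit)
      sigres$id <- list(exposures = as.list(id_expo),
                        residual_norm = fit$residual_norm,
                        n_mutations = fit$n_mutations, source = "refit")
    }
    if (length(sigres)) sigres else NULL
  })

  if (!is.null(sbs_expo) && !is.null(id_expo)) {
    report$hrd <- with_stage("hrd", hrd_classify(sbs_expo, id_expo, config$hrd))
  }

  class(report) <- "case_report"
  if (!is.null(config$out_dir)) {
    write_case_report(report, config$out_dir)
    return(invisible(report))
  }
  report
}

strip_heavy <- function(report) {
  # machine report carries summaries, not full per-site tables
  if (!is.null(report$variants)) report$variants$retained <- NULL
  if (!is.null(report$loh)) report$loh$scan <- NULL
  report
}

#' Write a case report to disk
#'
#' Emits `<sample_id>.report.json` (versioned machine report) and
#' `<sample_id>.summary.tsv` (one row mirroring a per-tumor summary table:
#' per-gene LOH verdicts, top SBS/ID exposures and the HRD call). Output is
#' byte-stable for a fixed configuration and seed.
#'
#' @param report A `case_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisible character vector of the written paths.
#' @export
write_case_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(out_dir, paste0(report$sample_id, ".report.json"))
  jsonlite::write_json(strip_heavy(unclass(report)), json_path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  fmt_expo <- function(e, hide_below = 1e-4) {
    if (is.null(e)) return(NA)
    v <- unlist(e$exposures)
    v <- sort(v[v >= hide_below], decreasing = TRUE)
    paste(sprintf("%s (%.1f%%)", names(v), 100 * v), collapse = ", ")
  }
  genes <- report$loh$genes
  row <- data.frame(
    sample_id = report$sample_id,
    stringsAsFactors = FALSE
  )
  for (g in names(genes)) row[[paste0("LOH_", g)]] <- genes[[g]]
  row$n_loh_regions <- if (is.null(report$loh)) NA else nrow(report$loh$regions)
  row$sbs_exposures <- fmt_expo(report$signatures$sbs)
  row$id_exposures <- fmt_expo(report$signatures$id)
  row$hrd <- if (is.null(report$hrd)) NA else report$hrd$call
  tsv_path <- file.path(out_dir, paste0(report$sample_id, ".summary.tsv"))
  utils::write.table(row, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(json_path, tsv_path))
}

#' @export
print.case_report <- function(x, ...) {
  cat("Case report for", x$sample_id, "(schema", x$schema_version, ")\n")
  if (!is.null(x$variants)) {
    cat(sprintf("  variants: %d caller A, %d caller B, %d consensus, %d retained\n",
                x$variants$n_caller_a, x$variants$n_caller_b,
                x$variants$n_consensus, x$variants$n_retained))
  }
  if (!is.null(x$loh)) {
    cat(sprintf("  LOH: %d/%d informative sites support LOH, %d region(s)\n",
                x$loh$n_supporting, x$loh$n_informative, nrow(x$loh$regions)))
    for (g in names(x$loh$genes)) cat("    ", g, ": ", x$loh$genes[[g]], "\n",
                                      sep = "")
  }
  if (!is.null(x$hrd)) {
    cat("  HRD:", x$hrd$call, "-", paste(x$hrd$reasons, collapse = "; "), "\n")
  }
  invisible(x)
}
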