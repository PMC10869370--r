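GENOTYPE_LEVELS <- c("carrier", "obligate_carrier", "wildtype", "unknown",
                     "not_tested")

normalize_genotype <- function(x, row = NA) {
  key <- gsub("[ _-]+", "_", tolower(trimws(x)))
  map <- c(carrier = "carrier", obligate_carrier = "obligate_carrier",
           wildtype = "wildtype", wt = "wildtype", unknown = "unknown",
           not_tested = "not_tested", na = "not_tested")
  key[key == "" | is.na(key)] <- "na"
  out <- unname(map[key])
  if (any(is.na(out))) {
    bad <- which(is.na(out))[1]
    stop("unknown genotype token '", x[bad], "' at row ",
         if (length(row) >= bad) row[bad] else bad)
  }
  out
}

SERRATED_HISTOLOGIES <- c("hyperplastic", "SSL", "TSA")

#' Load a family/phenotype table
#'
#' Reads the long-format family CSV: one row per event (cancer diagnosis or
#' polyp) or per event-free person. Expected columns: `person_id`, `sex`,
#' `brca1`, `rnf43`, `age_last_contact`, `record_type`
#' (`diagnosis`/`polyp`/`none`), `age`, `tumor_type`, `location`,
#' `histology`, `size_min_mm`, `size_max_mm`, `count`, `lesion_background`.
#' Genotype tokens are normalized to
#' carrier / obligate_carrier / wildtype / unknown / not_tested.
#'
#' The packaged family table transcribing the study family ships at
#' `system.file("extdata", "family_table1.csv", package = "lohsig")`.
#'
#' @param path CSV path.
#' @return A `family_table`: list of members, each with `person_id`, `sex`,
#'   `genotype_brca1`, `genotype_rnf43`, `age_last_contact`, `diagnoses`
#'   (data.frame) and `polyps` (data.frame).
#' @export
load_family_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(person_id = "character"))
  members <- list()
  if (nrow(df) == 0L) return(structure(members, class = "family_table"))
  df$brca1 <- normalize_genotype(df$brca1, seq_len(nrow(df)))
  df$rnf43 <- normalize_genotype(df$rnf43, seq_len(nrow(df)))
  for (pid in unique(df$person_id)) {
    rows <- df[df$person_id == pid, , drop = FALSE]
    dx <- rows[rows$record_type == "diagnosis", , drop = FALSE]
    pp <- rows[rows$record_type == "polyp", , drop = FALSE]
    pp$count[is.na(pp$count)] <- 1L
    # single-size records carry the same value in both columns
    pp$size_min_mm <- ifelse(is.na(pp$size_min_mm), pp$size_max_mm, pp$size_min_mm)
    pp$size_max_mm <- ifelse(is.na(pp$size_max_mm), pp$size_min_mm, pp$size_max_mm)
    if (any(pp$size_min_mm > pp$size_max_mm, na.rm = TRUE)) {
      stop("size_min_mm > size_max_mm for person ", pid)
    }
    lb <- pp$lesion_background
    if (is.null(lb)) lb <- rep(FALSE, nrow(pp))
    members[[pid]] <- list(
      person_id = pid, sex = rows$sex[1],
      genotype_brca1 = rows$brca1[1], genotype_rnf43 = rows$rnf43[1],
      age_last_contact = rows$age_last_contact[1],
      diagnoses = dx[, c("age", "tumor_type", "location", "histology"),
                     drop = FALSE],
      polyps = data.frame(age = pp$age, location = pp$location,
                          histology = pp$histology,
                          size_min_mm = pp$size_min_mm,
                          size_max_mm = pp$size_max_mm,
                          count = pp$count,
                          lesion_background = as.logical(lb),
                          stringsAsFactors = FALSE)
    )
  }
  structure(members, class = "family_table")
}

is_carrier <- function(genotype) genotype %in% c("carrier", "obligate_carrier")

#' Carrier and segregation counts for a family
#'
#' Counts carriers of each variant (obligate carriers count as carriers),
#' dual carriers, and among dual carriers those with at least one malignancy
#' diagnosis and at least one colorectal cancer (`tumor_type == "CRC"`).
#'
#' @param members A `family_table` from [load_family_table()].
#' @return Named integer vector: `brca1_carriers`, `rnf43_carriers`,
#'   `dual_carriers`, `dual_carriers_cancer_affected`, `dual_carriers_crc`.
#' @export
carrier_summary <- function(members) {
  b <- vapply(members, function(m) is_carrier(m$genotype_brca1), logical(1))
  r <- vapply(members, function(m) is_carrier(m$genotype_rnf43), logical(1))
  cancer <- vapply(members, function(m) nrow(m$diagnoses) > 0, logical(1))
  crc <- vapply(members, function(m) any(m$diagnoses$tumor_type == "CRC"),
                logical(1))
  c(brca1_carriers = sum(b), rnf43_carriers = sum(r),
    dual_carriers = sum(b & r),
    dual_carriers_cancer_affected = sum(b & r & cancer),
    dual_carriers_crc = sum(b & r & crc))
}

#' WHO-2019 serrated polyposis criteria configuration
#'
#' @param proximal_segments Segment labels counted as proximal to the rectum;
#'   `NULL` (default) means every colonic segment except `"rectum"` (sigmoid
#'   counts as proximal).
#' @param size_rule How a size range such as 6-8 mm qualifies against a
#'   threshold: by its `"lower_bound"` (default, conservative),
#'   `"upper_bound"`, or `"midpoint"`. Records without a size never qualify
#'   under `lower_bound`.
#' @param include_lesion_background_ssl Count serrated lesions recorded as
#'   the background of a carcinoma (default `TRUE`).
#' @return An `sps_config` list.
#' @export
sps_config <- function(proximal_segments = NULL,
                       size_rule = c("lower_bound", "upper_bound", "midpoint"),
                       include_lesion_background_ssl = TRUE) {
  structure(list(proximal_segments = proximal_segments,
                 size_rule = match.arg(size_rule),
                 include_lesion_background_ssl = include_lesion_background_ssl),
            class = "sps_config")
}

polyp_size_for_rule <- function(polyps, rule) {
  switch(rule,
         lower_bound = polyps$size_min_mm,
         upper_bound = polyps$size_max_mm,
         midpoint = (polyps$size_min_mm + polyps$size_max_mm) / 2)
}

#' Evaluate the WHO-2019 serrated polyposis syndrome criteria
#'
#' Criterion 1: five or more serrated polyps (hyperplastic, SSL or TSA)
#' proximal to the rectum, all 5 mm or greater in size, with two or more
#' 10 mm or greater. Criterion 2: more than 20 serrated polyps of any size
#' in the large bowel, with five or more proximal to the rectum. Polyp
#' history is cumulative over all ages.
#'
#' @param member One member of a `family_table`.
#' @param cfg An [sps_config()].
#' @return list with `meets_criterion_1`, `meets_criterion_2`, `meets_any`,
#'   and the serrated polyp counts used.
#' @export
sps_who2019 <- function(member, cfg = sps_config()) {
  pp <- member$polyps
  if (is.null(pp) || nrow(pp) == 0L) {
    return(list(meets_criterion_1 = FALSE, meets_criterion_2 = FALSE,
                meets_any = FALSE, n_serrated = 0L, n_proximal_ge5mm = 0L,
                n_proximal_ge10mm = 0L))
  }
  serrated <- pp$histology %in% SERRATED_HISTOLOGIES
  if (!cfg$include_lesion_background_ssl) serrated <- serrated & !pp$lesion_background
  pp <- pp[serrated, , drop = FALSE]
  proximal <- if (is.null(cfg$proximal_segments)) {
    tolower(pp$location) != "rectum"
  } else {
    pp$location %in% cfg$proximal_segments
  }
  size <- polyp_size_for_rule(pp, cfg$size_rule)
  ge5 <- !is.na(size) & size >= 5
  ge10 <- !is.na(size) & size >= 10
  n_serrated <- sum(pp$count)
  n_proximal <- sum(pp$count[proximal])
  n_prox_ge5 <- sum(pp$count[proximal & ge5])
  n_prox_ge10 <- sum(pp$count[proximal & ge10])
  crit1 <- n_prox_ge5 >= 5 && n_prox_ge10 >= 2
  crit2 <- n_serrated > 20 && n_proximal >= 5
  list(meets_criterion_1 = crit1, meets_criterion_2 = crit2,
       meets_any = crit1 || crit2, n_serrated = n_serrated,
       n_proximal_ge5mm = n_prox_ge5, n_proximal_ge10mm = n_prox_ge10)
}

#' Evaluate SPS criteria for every family member
#'
#' @param members A `family_table`.
#' @param cfg An [sps_config()].
#' @return data.frame with one row per member and the criterion flags.
#' @export
sps_screen <- function(members, cfg = sps_config()) {
  rows <- lapply(members, function(m) {
    r <- sps_who2019(m, cfg)
    data.frame(person_id = m$person_id,
               meets_criterion_1 = r$meets_criterion_1,
               meets_criterion_2 = r$meets_criterion_2,
               meets_any = r$meets_any, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
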