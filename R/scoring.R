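#' Binarize an indicator at a prognostic cutoff
#'
#' Returns 1 for the favorable stratum and 0 for the unfavorable one.
#' When high values are favorable, the favorable stratum is strictly above
#' the cutoff (`value > cutoff`); a value exactly at the cutoff falls in
#' the low stratum. The strictly-greater boundary convention is fixed and
#' applies symmetrically when low values are favorable. Missing or flagged
#' indicator values propagate to a missing score.
#'
#' @param value numeric indicator values.
#' @param cutoff scalar cutoff.
#' @param favorable_high are high values the favorable stratum
#'   (default `TRUE`)?
#' @return Integer vector of 0/1 (NA propagated).
#' @export
binarize_indicator <- function(value, cutoff, favorable_high = TRUE) {
  if (is.na(cutoff)) stop("cutoff is undefined for this indicator", call. = FALSE)
  high <- value > cutoff
  out <- if (favorable_high) high else !high
  as.integer(out)
}

#' Binary favorability of the tumor growth pattern
#'
#' A pushing tumor margin is the favorable category (1); an infiltrative
#' margin is unfavorable (0). Labels are normalized (case-insensitive,
#' with or without a trailing "margin") before mapping.
#'
#' @param growth_pattern character vector.
#' @return Integer 0/1 vector (NA propagated).
#' @export
growth_pattern_bin <- function(growth_pattern) {
  norm <- trimws(sub("margin$", "", trimws(tolower(as.character(growth_pattern)))))
  out <- ifelse(norm == "pushing", 1L, ifelse(norm == "infiltrative", 0L, NA_integer_))
  bad <- !is.na(growth_pattern) & is.na(out)
  if (any(bad))
    stop("unknown growth pattern value(s): ",
         paste(unique(growth_pattern[bad]), collapse = ", "),
         " (expected pushing or infiltrative)", call. = FALSE)
  out
}

#' Combine binary strata into the CD8-CD20 and immuno-interface scores
#'
#' The CD8-CD20 Immunogradient score is the sum of the binary CD8 CM and
#' CD20 CM strata (0-2); the immuno-interface score (IIS) additionally
#' adds the binary growth-pattern term (0-3). A missing component makes
#' the scores that depend on it missing.
#'
#' @param cd8_bin,cd20_bin,growth_bin 0/1 integer vectors.
#' @return Data frame with columns `cd8_cm_bin`, `cd20_cm_bin`,
#'   `growth_bin`, `cd8cd20_score`, `iis`.
#' @examples
#' combine_scores(1, 1, 1)  # cd8cd20 = 2, iis = 3
#' @export
combine_scores <- function(cd8_bin, cd20_bin, growth_bin) {
  chk <- function(x, nm) {
    if (any(!is.na(x) & !x %in% c(0L, 1L)))
      stop(nm, " must be 0/1", call. = FALSE)
    as.integer(x)
  }
  cd8_bin <- chk(cd8_bin, "cd8_bin")
  cd20_bin <- chk(cd20_bin, "cd20_bin")
  growth_bin <- chk(growth_bin, "growth_bin")
  cd8cd20 <- cd8_bin + cd20_bin
  data.frame(cd8_cm_bin = cd8_bin, cd20_cm_bin = cd20_bin,
             growth_bin = growth_bin,
             cd8cd20_score = cd8cd20, iis = cd8cd20 + growth_bin)
}

#' Score a cohort: cutoffs, binary strata, combined scores, KM summaries
#'
#' Learns optimal log-rank cutoffs for the CD8 and CD20 Center-of-Mass
#' indicators on the cohort (or uses externally supplied cutoffs, which
#' avoids the optimism of in-sample cutoff selection followed by in-sample
#' survival curves; the mode used is recorded in the result), binarizes
#' the indicators with the favorable direction taken from the cutoff
#' result, maps the growth pattern, and builds the CD8-CD20 Immunogradient
#' score and the IIS together with per-group Kaplan-Meier summaries.
#'
#' @param cohort data frame with columns `OS_months`, `event`,
#'   `growth_pattern`, and the indicator columns.
#' @param cd8_col,cd20_col indicator column names (default `CD8_CM`,
#'   `CD20_CM`).
#' @param cutoffs optional named list/vector with elements `cd8` and
#'   `cd20`; when `NULL` (default) cutoffs are learned by
#'   [optimal_cutoff()].
#' @param favorable_high named logical: is the high stratum favorable?
#'   Only used with external cutoffs; learned cutoffs carry their own
#'   direction.
#' @param min_group_frac group-size floor for the cutoff scan.
#' @param t_months landmark for the KM summaries (default 60 = 5 years).
#' @return List with `cohort` (input plus bin/score columns), `cutoffs`,
#'   `cutoff_mode` (`"learned"` or `"external"`), `km_cd8cd20`, `km_iis`
#'   (see [km_logrank()]).
#' @export
score_cohort <- function(cohort, cd8_col = "CD8_CM", cd20_col = "CD20_CM",
                         cutoffs = NULL,
                         favorable_high = c(cd8 = TRUE, cd20 = TRUE),
                         min_group_frac = 0.10, t_months = 60) {
  stopifnot(all(c("OS_months", "event", "growth_pattern") %in% names(cohort)))
  if (is.null(cutoffs)) {
    co8 <- optimal_cutoff(cohort[[cd8_col]], cohort$OS_months, cohort$event,
                          min_group_frac = min_group_frac, indicator = cd8_col)
    co20 <- optimal_cutoff(cohort[[cd20_col]], cohort$OS_months, cohort$event,
                           min_group_frac = min_group_frac, indicator = cd20_col)
    cutoffs <- list(cd8 = co8$cutoff, cd20 = co20$cutoff)
    favorable_high <- c(cd8 = co8$direction == "high_favorable",
                        cd20 = co20$direction == "high_favorable")
    mode <- "learned"
  } else {
    cutoffs <- as.list(cutoffs)
    mode <- "external"
  }
  cd8_bin <- binarize_indicator(cohort[[cd8_col]], cutoffs$cd8,
                                favorable_high[["cd8"]])
  cd20_bin <- binarize_indicator(cohort[[cd20_col]], cutoffs$cd20,
                                 favorable_high[["cd20"]])
  gb <- growth_pattern_bin(cohort$growth_pattern)
  sc <- combine_scores(cd8_bin, cd20_bin, gb)
  out <- cbind(cohort, sc)
  km2 <- km_logrank(out$OS_months, out$event, out$cd8cd20_score,
                    t_months = t_months)
  km3 <- km_logrank(out$OS_months, out$event, out$iis, t_months = t_months)
  list(cohort = out, cutoffs = cutoffs, favorable_high = favorable_high,
       cutoff_mode = mode, km_cd8cd20 = km2, km_iis = km3)
}
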