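#' Run the full per-case pipeline and write its artifacts
#'
#' Thin orchestration over [immunogradient()]: fits one case and writes
#' the hexagon-grid CSV (including ranks when an interface exists), the
#' one-row indicator CSV, a QC report JSON, and optionally an overlay
#' figure with the interface-zone aspect coloring (TE yellow, tumor aspect
#' red, stroma aspect green).
#'
#' @param tm a [tissue_map()] or path.
#' @param cells a [cell_table()] or CSV path.
#' @param out_dir output directory (created if needed).
#' @param case_id case identifier used in file names.
#' @param figure also write an overlay PNG (default `FALSE`).
#' @param ... passed to [immunogradient()].
#' @return The `immunogradient` fit, invisibly, with an attribute
#'   `artifacts` listing the files written.
#' @export
run_case <- function(tm, cells, out_dir, case_id = "case", figure = FALSE, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- immunogradient(tm, cells, ...)
  grid_csv <- file.path(out_dir, paste0(case_id, "_hexgrid.csv"))
  write_hex_grid(fit$grid, grid_csv)
  ind <- cbind(case_id = case_id, fit$indicators,
               qc_pass = fit$qc$pass, tumor_area_mm2 = fit$qc$tumor_area_mm2)
  ind_csv <- file.path(out_dir, paste0(case_id, "_indicators.csv"))
  utils::write.csv(ind, ind_csv, row.names = FALSE)
  qc_json <- file.path(out_dir, paste0(case_id, "_qc.json"))
  jsonlite::write_json(list(case_id = case_id, pass = fit$qc$pass,
                            tumor_area_mm2 = fit$qc$tumor_area_mm2,
                            reason = fit$qc$reason,
                            params = fit$params),
                       qc_json, auto_unbox = TRUE, pretty = TRUE, na = "null")
  artifacts <- c(grid_csv, ind_csv, qc_json)
  if (figure) {
    fig <- file.path(out_dir, paste0(case_id, "_overlay.png"))
    grDevices::png(fig, width = 900, height = 900)
    plot(fit, which = "map")
    grDevices::dev.off()
    artifacts <- c(artifacts, fig)
  }
  attr(fit, "artifacts") <- artifacts
  invisible(fit)
}

#' Run the cohort-level analysis
#'
#' Takes a cohort table holding survival outcomes, the growth pattern, and
#' the per-case indicators (e.g. assembled from [run_case()] outputs or
#' from [simulate_cohort()]), and produces the cohort statistics: a
#' univariate log-rank screen over the indicator columns (optimal cutoffs),
#' the combined scores with Kaplan-Meier summaries, and a stepwise
#' multivariate Cox model over the binarized screen-significant factors.
#' With too few cases or events the survival stages are skipped with an
#' explicit notice rather than an error.
#'
#' @param cohort data frame with `case_id`, `OS_months`, `event`,
#'   `growth_pattern`, and indicator columns.
#' @param indicator_cols indicator columns to screen; defaults to the
#'   `CD8_CM`/`CD20_CM` pair present in every cohort table.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param min_cases minimum cohort size for the survival stages
#'   (default 20).
#' @param min_group_frac group-size floor for cutoff scans.
#' @param t_months landmark for KM summaries.
#' @return List with `screen` (per-indicator cutoff results), `scores`
#'   (see [score_cohort()]), `cox` (stepwise model or `NULL`), `notices`.
#' @export
run_cohort <- function(cohort,
                       indicator_cols = intersect(c("CD8_CM", "CD20_CM"),
                                                  names(cohort)),
                       out_dir = NULL, min_cases = 20,
                       min_group_frac = 0.10, t_months = 60) {
  notices <- character(0)
  n <- nrow(cohort)
  n_events <- sum(cohort$event, na.rm = TRUE)
  if (n < min_cases || n_events < 2) {
    notices <- c(notices, sprintf(
      "survival statistics skipped: %d cases with %d events (need >= %d cases, >= 2 events)",
      n, n_events, min_cases))
    return(list(screen = NULL, scores = NULL, cox = NULL, notices = notices))
  }
  screen <- lapply(indicator_cols, function(col) {
    tryCatch(optimal_cutoff(cohort[[col]], cohort$OS_months, cohort$event,
                            min_group_frac = min_group_frac, indicator = col),
             no_cutoff_error = function(e) {
               notices <<- c(notices, paste0(col, ": ", conditionMessage(e)))
               NULL
             })
  })
  names(screen) <- indicator_cols
  scores <- score_cohort(cohort, min_group_frac = min_group_frac,
                         t_months = t_months)
  sc <- scores$cohort
  cox <- tryCatch(
    cox_model(sc, covariates = c("cd8_cm_bin", "cd20_cm_bin", "growth_bin"),
              stepwise = TRUE),
    error = function(e) {
      notices <<- c(notices, paste("Cox model failed:", conditionMessage(e)))
      NULL
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(sc, file.path(out_dir, "cohort_scored.csv"),
                     row.names = FALSE)
    cut_tab <- do.call(rbind, lapply(Filter(Negate(is.null), screen),
      function(cr) data.frame(indicator = cr$indicator, cutoff = cr$cutoff,
                              p = cr$p, direction = cr$direction)))
    utils::write.csv(cut_tab, file.path(out_dir, "cutoffs.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(km_cd8cd20 = scores$km_cd8cd20$table,
           km_iis = scores$km_iis$table,
           cox_terms = if (!is.null(cox)) cox$terms,
           cox_lr = if (!is.null(cox)) cox$model_lr,
           notices = notices),
      file.path(out_dir, "cohort_report.json"),
      auto_unbox = TRUE, pretty = TRUE, na = "null")
  }
  list(screen = screen, scores = scores, cox = cox, notices = notices)
}
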