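#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided exact p-value obtained by summing the probabilities of all
#' tables (with the observed margins fixed) whose hypergeometric
#' probability does not exceed that of the observed table, as implemented
#' in [stats::fisher.test()]. The reported odds ratio is the conditional
#' maximum-likelihood estimate (not the sample cross-product ratio).
#'
#' @param tab 2x2 matrix of non-negative integer counts; both margins must
#'   be positive.
#' @return List with `odds_ratio` and `p` (two-sided).
#' @examples
#' fisher_exact_2x2(matrix(c(10, 10, 10, 10), 2))$p  # 1: no association
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) || any(tab != round(tab)))
    stop("`tab` must be a 2x2 matrix of non-negative integer counts", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop(structure(class = c("degenerate_table_error", "error", "condition"),
                   list(message = "degenerate table: a margin is zero",
                        call = NULL)))
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Compare an indicator across groups
#'
#' Cell-density indicators are heavily right-skewed, so by default values
#' are transformed as `ln(x + offset)` before parametric testing. Returns
#' one-way ANOVA (F, p), Welch pairwise t-tests with Bonferroni adjustment
#' (`p_adj = min(1, k * p_raw)` over the `k` pairs), the overall Welch test
#' for two-group calls, and a Kolmogorov-Smirnov normality note on the
#' standardized within-group residuals.
#'
#' @param values numeric vector.
#' @param group factor/vector of group labels (>= 2 groups, each n >= 2).
#' @param log_transform apply `ln(x + offset)` first (default `TRUE`).
#' @param offset offset inside the log (default 1, so zero densities map
#'   to zero).
#' @return A `group_comparison` list: `anova_F`, `anova_p`, `pairwise`
#'   (data frame with raw and Bonferroni-adjusted p), `welch` (for 2
#'   groups), `ks_normality_p`, `degenerate`.
#' @export
compare_groups <- function(values, group, log_transform = TRUE, offset = 1) {
  group <- factor(group)
  ok <- is.finite(values) & !is.na(group)
  values <- values[ok]; group <- droplevels(group[ok])
  if (nlevels(group) < 2L || any(table(group) < 2L))
    stop("need >= 2 groups with n >= 2 each", call. = FALSE)
  x <- if (log_transform) log(values + offset) else values

  v <- tapply(x, group, stats::var)
  if (all(v == 0)) {
    pairs <- t(utils::combn(levels(group), 2L))
    return(structure(list(
      anova_F = 0, anova_p = 1,
      pairwise = data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                            t = 0, p_raw = 1, p_bonferroni = 1),
      welch = NULL, ks_normality_p = NA_real_, degenerate = TRUE),
      class = "group_comparison"))
  }

  fit <- stats::aov(x ~ group)
  an <- summary(fit)[[1]]
  pairs <- t(utils::combn(levels(group), 2L))
  k <- nrow(pairs)
  pw <- lapply(seq_len(k), function(i) {
    a <- x[group == pairs[i, 1]]; b <- x[group == pairs[i, 2]]
    if (stats::var(a) == 0 && stats::var(b) == 0)
      return(c(t = 0, p = if (mean(a) == mean(b)) 1 else 0))
    tt <- stats::t.test(a, b)            # Welch by default
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  pw <- do.call(rbind, pw)
  pairwise <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                         t = pw[, "t"], p_raw = pw[, "p"],
                         p_bonferroni = pmin(1, k * pw[, "p"]))
  welch <- if (nlevels(group) == 2L) {
    tt <- stats::t.test(x ~ group)
    list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
  }
  res <- unlist(tapply(x, group, function(g) (g - mean(g)) / stats::sd(g)))
  ks <- suppressWarnings(stats::ks.test(res, "pnorm"))
  structure(list(anova_F = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
                 pairwise = pairwise, welch = welch,
                 ks_normality_p = ks$p.value, degenerate = FALSE),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison: ANOVA F = %.3f, p = %.4g%s\n",
              x$anova_F, x$anova_p,
              if (x$degenerate) " (degenerate: zero variance)" else ""))
  if (!is.null(x$welch))
    cat(sprintf("  Welch t = %.3f (df %.1f), p = %.4g\n",
                x$welch$t, x$welch$df, x$welch$p))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Optimal log-rank cutoff for a prognostic indicator
#'
#' Scans every midpoint between consecutive distinct indicator values whose
#' split leaves both groups with at least `min_group_frac` of the cohort,
#' computes the two-group log-rank statistic at each candidate, and returns
#' the cutoff minimizing the log-rank p-value (ties broken toward the
#' smaller cutoff). The returned p is the raw minimum over the scan, with
#' no multiple-testing correction; it is marked exploratory in the result
#' so the optimism of in-sample cutoff selection stays visible.
#'
#' @param values numeric indicator values.
#' @param time,event survival time (months) and event indicator (0/1).
#' @param min_group_frac minimum fraction of patients per group
#'   (default 0.10).
#' @param indicator name recorded in the result.
#' @return A `cutoff_result` list: `indicator`, `cutoff`, `n_low`,
#'   `n_high`, `chisq`, `p`, `direction` (`"high_favorable"` or
#'   `"high_unfavorable"`), `exploratory = TRUE`, and the scanned
#'   `candidates` data frame.
#' @export
optimal_cutoff <- function(values, time, event, min_group_frac = 0.10,
                           indicator = deparse(substitute(values))) {
  ok <- is.finite(values) & is.finite(time) & !is.na(event)
  values <- values[ok]; time <- time[ok]; event <- as.integer(event[ok])
  n <- length(values)
  if (n < 20L) warning("fewer than 20 patients for cutoff optimization")
  if (sum(event) < 2L)
    stop("need at least 2 events for cutoff optimization", call. = FALSE)
  sv <- sort(unique(values))
  if (length(sv) < 2L)
    stop(structure(class = c("no_cutoff_error", "error", "condition"),
                   list(message = "constant indicator: no admissible cutoff",
                        call = NULL)))
  cand <- (sv[-1] + sv[-length(sv)]) / 2
  nmin <- min_group_frac * n
  keep <- vapply(cand, function(cut) {
    nh <- sum(values > cut); nl <- n - nh
    nh >= nmin && nl >= nmin
  }, logical(1))
  cand <- cand[keep]
  if (!length(cand))
    stop(structure(class = c("no_cutoff_error", "error", "condition"),
                   list(message = "no admissible cutoff under the group-size floor",
                        call = NULL)))
  scan <- t(vapply(cand, function(cut) {
    grp <- values > cut
    sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
    p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    # obs < exp in the high group means fewer deaths than expected: favorable
    c(chisq = sd$chisq, p = p, high_fav = as.numeric(sd$obs[2] < sd$exp[2]))
  }, numeric(3)))
  best <- which(scan[, "p"] == min(scan[, "p"]))[1]
  structure(list(indicator = indicator, cutoff = cand[best],
                 n_low = sum(values <= cand[best]),
                 n_high = sum(values > cand[best]),
                 chisq = unname(scan[best, "chisq"]),
                 p = unname(scan[best, "p"]),
                 direction = if (scan[best, "high_fav"] > 0)
                   "high_favorable" else "high_unfavorable",
                 exploratory = TRUE,
                 candidates = data.frame(cutoff = cand,
                                         chisq = scan[, "chisq"],
                                         p = scan[, "p"])),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("Optimal log-rank cutoff for %s: %.4g (n_low %d / n_high %d)\n",
              x$indicator, x$cutoff, x$n_low, x$n_high))
  cat(sprintf("  chisq = %.3f, p = %.4g (%s; exploratory, uncorrected scan minimum)\n",
              x$chisq, x$p, x$direction))
  invisible(x)
}

#' Kaplan-Meier curves, t-year survival and the log-rank test
#'
#' Product-limit survival estimates per stratum, the survival probability
#' at a landmark time read from the right-continuous step function (5-year
#' overall survival is read at exactly 60 months), and the k-group
#' log-rank test. Empty strata are dropped with a warning.
#'
#' @param time,event survival time (months) and event indicator.
#' @param strata stratum labels.
#' @param t_months landmark time(s) for survival read-off (default 60).
#' @return List with `fit` (a [survival::survfit()] object), `table`
#'   (per-stratum n, events, and survival at each landmark), `chisq`,
#'   `df`, `p` (log-rank; `NA` with a single stratum).
#' @export
km_logrank <- function(time, event, strata, t_months = 60) {
  strata <- factor(strata)
  ok <- is.finite(time) & !is.na(event) & !is.na(strata)
  time <- time[ok]; event <- as.integer(event[ok])
  strata <- droplevels(strata[ok])
  empty <- setdiff(levels(strata), unique(as.character(strata)))
  if (length(empty)) warning("dropping empty strata: ", paste(empty, collapse = ", "))
  fit <- survival::survfit(survival::Surv(time, event) ~ strata)
  sm <- summary(fit, times = t_months, extend = TRUE)
  surv_mat <- matrix(sm$surv, ncol = length(t_months), byrow = FALSE)
  lv <- levels(strata)
  if (length(lv) == 1L) {
    tab <- data.frame(stratum = lv, n = length(time), events = sum(event))
  } else {
    tab <- data.frame(stratum = sub("^strata=", "", names(fit$strata)),
                      n = as.integer(fit$n),
                      events = as.integer(tapply(event, strata, sum)[sub("^strata=", "", names(fit$strata))]))
  }
  for (j in seq_along(t_months))
    tab[[sprintf("surv_%gm", t_months[j])]] <-
      if (length(lv) == 1L) sm$surv[j] else
        sm$surv[seq(j, length(sm$surv), by = length(t_months))]
  if (length(lv) >= 2L) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ strata)
    df <- length(sd$n) - 1L
    list(fit = fit, table = tab, chisq = sd$chisq, df = df,
         p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
  } else {
    list(fit = fit, table = tab, chisq = NA_real_, df = 0L, p = NA_real_)
  }
}

# log partial likelihood of a fitted coxph model evaluated at fixed
# coefficients beta on (possibly different) data
.cox_loglik_at <- function(formula, data, beta) {
  fit <- survival::coxph(formula, data = data, ties = "efron",
                         init = beta,
                         control = survival::coxph.control(iter.max = 0))
  fit$loglik[length(fit$loglik)]
}

#' Cox proportional hazards model with stepwise likelihood-ratio selection
#'
#' Fits a Cox model (Efron tie handling) for overall survival on the given
#' covariates. With `stepwise = TRUE`, terms are selected by
#' likelihood-ratio tests: forward steps add the candidate with the
#' smallest LR p-value while it is below `alpha_enter`, each followed by
#' backward checks removing any included term whose LR p-value rises above
#' `alpha_remove`, until the model is stable. Zero-variance covariates are
#' excluded with a warning, as is an event count below five per candidate
#' term.
#'
#' @param data data frame containing the covariates.
#' @param time,event column names (or vectors) for survival time and event.
#' @param covariates character vector of candidate covariate names.
#' @param stepwise run stepwise LR selection (default `FALSE`: fit all).
#' @param alpha_enter,alpha_remove LR p-value thresholds (default 0.05).
#' @return A `cox_model_result`: `terms` (data frame with term, HR, 95% CI
#'   bounds, p), `model_lr`, `model_lr_df`, `model_lr_p`, `selected`,
#'   `trace` (selection log), and the underlying `fit`.
#' @export
cox_model <- function(data, time = "OS_months", event = "event",
                      covariates, stepwise = FALSE,
                      alpha_enter = 0.05, alpha_remove = 0.05) {
  tt <- if (is.character(time)) data[[time]] else time
  ev <- if (is.character(event)) data[[event]] else event
  df <- data.frame(.time = tt, .event = as.integer(ev),
                   data[, covariates, drop = FALSE])
  if (anyNA(df))
    stop("missing values in survival columns or covariates; ",
         "complete cases are required", call. = FALSE)
  novar <- covariates[vapply(covariates, function(v) {
    x <- df[[v]]
    length(unique(x)) < 2L
  }, logical(1))]
  if (length(novar)) {
    warning("excluding zero-variance covariate(s): ",
            paste(novar, collapse = ", "))
    covariates <- setdiff(covariates, novar)
  }
  if (!length(covariates)) stop("no usable covariates", call. = FALSE)
  if (sum(df$.event) < 5 * length(covariates))
    warning(sprintf("only %d events for %d candidate terms (< 5 per term)",
                    sum(df$.event), length(covariates)))

  form <- function(vars) stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    if (length(vars)) paste(vars, collapse = " + ") else "1"))
  fit_ll <- function(vars) {
    if (!length(vars)) {
      f0 <- survival::coxph(form(character(0)), data = df, ties = "efron")
      return(list(fit = f0, ll = f0$loglik[1]))
    }
    f <- survival::coxph(form(vars), data = df, ties = "efron")
    list(fit = f, ll = f$loglik[2])
  }

  trace <- character(0)
  if (stepwise) {
    current <- character(0)
    cur <- fit_ll(current)
    repeat {
      changed <- FALSE
      # forward
      cands <- setdiff(covariates, current)
      if (length(cands)) {
        ps <- vapply(cands, function(v) {
          try_fit <- tryCatch(fit_ll(c(current, v)), error = function(e) NULL)
          if (is.null(try_fit)) return(NA_real_)
          df_add <- length(try_fit$fit$coefficients) -
            length(cur$fit$coefficients %||% numeric(0))
          stats::pchisq(2 * (try_fit$ll - cur$ll), df = max(df_add, 1L),
                        lower.tail = FALSE)
        }, numeric(1))
        if (any(is.finite(ps)) && min(ps, na.rm = TRUE) < alpha_enter) {
          add <- cands[which.min(ps)]
          current <- c(current, add)
          cur <- fit_ll(current)
          trace <- c(trace, sprintf("+ %s (LR p = %.4g)", add, min(ps, na.rm = TRUE)))
          changed <- TRUE
        }
      }
      # backward
      repeat {
        if (length(current) < 1L) break
        ps <- vapply(current, function(v) {
          red <- fit_ll(setdiff(current, v))
          df_drop <- length(cur$fit$coefficients) -
            length(red$fit$coefficients %||% numeric(0))
          stats::pchisq(2 * (cur$ll - red$ll), df = max(df_drop, 1L),
                        lower.tail = FALSE)
        }, numeric(1))
        if (max(ps) > alpha_remove) {
          dropv <- current[which.max(ps)]
          current <- setdiff(current, dropv)
          cur <- fit_ll(current)
          trace <- c(trace, sprintf("- %s (LR p = %.4g)", dropv, max(ps)))
          changed <- TRUE
        } else break
      }
      if (!changed) break
    }
    selected <- current
  } else {
    selected <- covariates
  }

  if (!length(selected)) {
    return(structure(list(terms = data.frame(), selected = character(0),
                          model_lr = 0, model_lr_df = 0L, model_lr_p = 1,
                          trace = trace, fit = NULL),
                     class = "cox_model_result"))
  }
  fit <- survival::coxph(form(selected), data = df, ties = "efron")
  if (!is.null(fit$info) || any(!is.finite(fit$coefficients)))
    stop("Cox model failed to converge", call. = FALSE)
  if (any(abs(fit$coefficients) > 15))
    warning("monotone likelihood (separation) suspected: a coefficient diverges")
  s <- summary(fit)
  terms <- data.frame(term = rownames(s$conf.int),
                      HR = s$conf.int[, "exp(coef)"],
                      CI_low = s$conf.int[, "lower .95"],
                      CI_high = s$conf.int[, "upper .95"],
                      p = s$coefficients[, "Pr(>|z|)"],
                      row.names = NULL)
  lr <- 2 * (fit$loglik[2] - fit$loglik[1])
  structure(list(terms = terms, selected = selected,
                 model_lr = lr, model_lr_df = length(fit$coefficients),
                 model_lr_p = stats::pchisq(lr, length(fit$coefficients),
                                            lower.tail = FALSE),
                 trace = trace, fit = fit),
            class = "cox_model_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cox_model_result <- function(x, ...) {
  cat(sprintf("Cox model (Efron ties): LR = %.2f on %d df, p = %.4g\n",
              x$model_lr, x$model_lr_df, x$model_lr_p))
  if (nrow(x$terms)) {
    with(x$terms, for (i in seq_along(term))
      cat(sprintf("  %-28s HR %6.3f (%.3f-%.3f), p = %.4g\n",
                  term[i], HR[i], CI_low[i], CI_high[i], p[i])))
  } else cat("  (null model: no terms selected)\n")
  if (length(x$trace)) cat("  selection:", paste(x$trace, collapse = "; "), "\n")
  invisible(x)
}

#' Leave-one-out cross-validation of a Cox model specification
#'
#' For each patient, the model is refitted on the remaining n-1 patients
#' and the linear predictor of the held-out patient is recorded.
#'
#' The cross-validated concordance index scores every comparable pair
#' (Harrell rules: distinct observed times with the earlier one an event)
#' under the two leave-one-out models that each exclude one pair member,
#' averaging the two verdicts; comparisons with tied predicted risks are
#' excluded. Scoring a pair only within a single model's risk ordering
#' avoids the anti-conservative bias that pooling linear predictors across
#' leave-one-out models induces under a null model, and excluding ties
#' lets a perfectly separating binary factor reach concordance 1.
#'
#' The cross-validated partial log-likelihood follows Verweij-van
#' Houwelingen: the sum over patients of the full-data partial
#' log-likelihood at the leave-one-out coefficients minus the reduced-data
#' one. Refit failures flag the patient and reduce the completion fraction
#' instead of aborting.
#'
#' @inheritParams cox_model
#' @return List with `concordance`, `cv_partial_loglik`, `linear_predictor`
#'   (per patient, NA when the refit failed), `completed` (fraction of
#'   successful refits) and `failed` (row indices).
#' @export
loo_cross_validate <- function(data, time = "OS_months", event = "event",
                               covariates) {
  tt <- if (is.character(time)) data[[time]] else time
  ev <- if (is.character(event)) data[[event]] else event
  df <- data.frame(.time = tt, .event = as.integer(ev),
                   data[, covariates, drop = FALSE])
  if (anyNA(df)) stop("complete cases are required", call. = FALSE)
  n <- nrow(df)
  form <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                  paste(covariates, collapse = " + ")))
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(covariates, collapse = " + "))), df)
  X <- X[, -1, drop = FALSE]
  lp <- rep(NA_real_, n)
  betas <- vector("list", n)
  cvpl <- 0
  failed <- integer(0)
  for (i in seq_len(n)) {
    fit_i <- tryCatch(
      suppressWarnings(survival::coxph(form, data = df[-i, , drop = FALSE],
                                       ties = "efron")),
      error = function(e) NULL)
    if (is.null(fit_i) || any(!is.finite(fit_i$coefficients))) {
      failed <- c(failed, i); next
    }
    lp[i] <- unname(stats::predict(fit_i, newdata = df[i, , drop = FALSE],
                                   type = "lp"))
    betas[[i]] <- fit_i$coefficients
    ll_all <- .cox_loglik_at(form, df, beta = fit_i$coefficients)
    cvpl <- cvpl + (ll_all - fit_i$loglik[2])
  }
  # pair-averaged concordance: pair (i, j) scored under the models that
  # exclude i and exclude j, half weight each; tied risks skipped
  num <- 0; den <- 0
  tt_ <- df$.time; ee_ <- df$.event
  for (i in seq_len(n)) {
    if (is.null(betas[[i]])) next
    risk <- drop(X %*% betas[[i]])
    j <- seq_len(n)[-i]
    comparable <- (tt_[i] < tt_[j] & ee_[i] == 1L) |
      (tt_[j] < tt_[i] & ee_[j] == 1L)
    j <- j[comparable]
    if (!length(j)) next
    shorter_is_i <- tt_[i] < tt_[j]
    d <- risk[i] - risk[j]
    untied <- d != 0
    # concordant when the shorter survivor carries the higher risk
    conc_pair <- (shorter_is_i & d > 0) | (!shorter_is_i & d < 0)
    num <- num + 0.5 * sum(conc_pair[untied])
    den <- den + 0.5 * sum(untied)
  }
  conc <- if (den == 0) NA_real_ else num / den
  list(concordance = conc, cv_partial_loglik = cvpl,
       linear_predictor = lp, completed = 1 - length(failed) / n,
       failed = failed)
}

#' Cohort exclusion arithmetic
#'
#' Applies a set of named case-level exclusion counts to the number of
#' retrieved cases and returns the analyzed-cohort size, validating that
#' the exclusions are non-negative and do not exceed the cohort.
#'
#' @param n_retrieved number of retrieved cases.
#' @param exclusions named integer vector of exclusion counts (e.g.
#'   preoperative treatment, unresected metastasis, mucinous histology,
#'   appendiceal tumor, tumor area below the QC threshold).
#' @return List with `n_analyzed`, `n_excluded` and the exclusion `table`.
#' @examples
#' cohort_exclusions(99, c(preop_treatment = 2, unresected_metastasis = 3,
#'                         mucinous = 4, appendiceal = 1, small_tumor_area = 2))
#' @export
cohort_exclusions <- function(n_retrieved, exclusions) {
  stopifnot(n_retrieved >= 0, all(exclusions >= 0),
            all(exclusions == round(exclusions)))
  tot <- sum(exclusions)
  if (tot > n_retrieved)
    stop("exclusions exceed the retrieved cohort", call. = FALSE)
  list(n_analyzed = as.integer(n_retrieved - tot),
       n_excluded = as.integer(tot),
       table = data.frame(reason = names(exclusions),
                          n = as.integer(exclusions)))
}
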