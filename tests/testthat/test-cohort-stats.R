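# Fisher tests, group comparisons, cutoff optimization, KM/log-rank,
# Cox models with stepwise selection, and leave-one-out validation.

test_that("Fisher's exact matches complete hypergeometric enumeration", {
  set.seed(3)
  for (i in 1:25) {
    tab <- matrix(sample(0:30, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    got <- fisher_exact_2x2(tab)$p
    expect_equal(got, fisher_enum_p(tab), tolerance = 1e-10)
  }
  expect_equal(fisher_exact_2x2(matrix(c(10, 10, 10, 10), 2))$p, 1)
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 5, 6), 2, byrow = TRUE)),
               class = "degenerate_table_error")
})

test_that("group comparison handles identical, separated and degenerate groups", {
  x <- rep(c(5, 5), each = 20)
  grp <- rep(c("a", "b"), each = 20)
  deg <- compare_groups(x, grp)
  expect_true(deg$degenerate)
  expect_equal(deg$anova_p, 1)
  expect_equal(deg$pairwise$p_bonferroni, 1)

  set.seed(9)
  y <- c(rnorm(50, 0), rnorm(50, 2))
  g2 <- rep(c("lo", "hi"), each = 50)
  res <- compare_groups(y, g2, log_transform = FALSE)
  expect_lt(res$welch$p, 1e-6)
  expect_lt(res$anova_p, 1e-6)
})

test_that("Bonferroni adjustment is min(1, k * p_raw) over the pairwise tests", {
  set.seed(13)
  vals <- c(rnorm(20, 0), rnorm(20, 0.5), rnorm(20, 3))
  grp <- rep(c("a", "b", "c"), each = 20)
  res <- compare_groups(vals, grp, log_transform = FALSE)
  k <- nrow(res$pairwise)
  expect_equal(k, 3)
  expect_equal(res$pairwise$p_bonferroni, pmin(1, k * res$pairwise$p_raw))
  # raw pairwise p agrees with a direct Welch test
  direct <- stats::t.test(vals[grp == "a"], vals[grp == "b"])$p.value
  expect_equal(res$pairwise$p_raw[res$pairwise$group1 == "a" &
                                    res$pairwise$group2 == "b"], direct)
})

test_that("log transform is applied as ln(x + offset)", {
  set.seed(4)
  v <- rexp(60, 0.01)
  g <- rep(c("a", "b"), each = 30)
  r1 <- compare_groups(v, g, log_transform = TRUE, offset = 1)
  r2 <- compare_groups(log(v + 1), g, log_transform = FALSE)
  expect_equal(r1$anova_F, r2$anova_F)
  expect_equal(r1$welch$p, r2$welch$p)
})

test_that("the optimal cutoff falls between well-separated risk clusters", {
  set.seed(21)
  n <- 60
  risk <- rep(c(0, 1), each = n / 2)
  values <- ifelse(risk == 1, rnorm(n, 10, 0.3), rnorm(n, 2, 0.3))
  time <- ifelse(risk == 1, rexp(n, 0.10), rexp(n, 0.005))
  res <- optimal_cutoff(values, time, rep(1, n))
  expect_gt(res$cutoff, 4); expect_lt(res$cutoff, 8)
  expect_equal(res$direction, "high_unfavorable")
  expect_lt(res$p, 1e-6)
  expect_true(res$exploratory)
})

test_that("cutoff scan equals an exhaustive brute-force recomputation", {
  set.seed(34)
  n <- 50
  values <- round(rnorm(n), 1)
  time <- rexp(n, 0.02 * exp(0.5 * values))
  event <- rbinom(n, 1, 0.8)
  res <- optimal_cutoff(values, time, event, min_group_frac = 0.1)
  sv <- sort(unique(values))
  cand <- (sv[-1] + sv[-length(sv)]) / 2
  best_p <- Inf; best_cut <- NA
  for (cut in cand) {
    nh <- sum(values > cut)
    if (nh < 5 || n - nh < 5) next
    sd <- survival::survdiff(survival::Surv(time, event) ~ (values > cut))
    p <- stats::pchisq(sd$chisq, 1, lower.tail = FALSE)
    if (p < best_p - 1e-14) { best_p <- p; best_cut <- cut }
  }
  expect_equal(res$cutoff, best_cut)
  expect_equal(res$p, best_p)
})

test_that("constant indicators and inadmissible scans raise a no-cutoff error", {
  tt <- rexp(30, 0.05)
  expect_error(suppressWarnings(optimal_cutoff(rep(3, 30), tt, rep(1, 30))),
               class = "no_cutoff_error")
  # two distinct values but a 1/29 split cannot satisfy the 10% floor
  v <- c(rep(1, 29), 2)
  expect_error(suppressWarnings(optimal_cutoff(v, tt, rep(1, 30))),
               class = "no_cutoff_error")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(40)
  t <- sort(rexp(80, 0.02))
  km <- km_logrank(t, rep(1, 80), rep("all", 80), t_months = c(20, 50))
  # survival at t equals fraction with time > t
  expect_equal(km$table$surv_20m, mean(t > 20))
  expect_equal(km$table$surv_50m, mean(t > 50))
  # duplicated stratum: log-rank statistic 0
  km2 <- km_logrank(c(t, t), rep(1, 160), rep(c("a", "b"), each = 80))
  expect_equal(km2$chisq, 0, tolerance = 1e-10)
  expect_equal(km2$p, 1, tolerance = 1e-10)
})

test_that("log-rank detects a hazard ratio of 2 at n = 500 per arm", {
  set.seed(41)
  t <- c(rexp(500, 0.02), rexp(500, 0.04))
  grp <- rep(c("ref", "double"), each = 500)
  cens <- runif(1000, 0, 100)
  km <- km_logrank(pmin(t, cens), as.integer(t <= cens), grp)
  expect_lt(km$p, 1e-4)
})

test_that("Cox recovers a true HR of 0.3 from simulated exponential survival", {
  set.seed(42)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.04 * 0.3^x)
  cens <- runif(n, 0, 120)
  d <- data.frame(OS_months = pmin(t, cens), event = as.integer(t <= cens), x = x)
  fit <- cox_model(d, covariates = "x")
  hr <- fit$terms$HR
  expect_gt(hr, 0.2); expect_lt(hr, 0.45)
  expect_true(fit$terms$CI_low < hr & hr < fit$terms$CI_high)
  expect_gt(fit$model_lr, 0)
})

test_that("zero-variance covariates are excluded with a warning", {
  set.seed(43)
  d <- data.frame(OS_months = rexp(50, 0.05), event = 1,
                  x = rnorm(50), z = rep(2, 50))
  expect_warning(fit <- cox_model(d, covariates = c("x", "z")), "zero-variance")
  expect_identical(fit$selected, "x")
})

test_that("stepwise selection keeps true effects and rarely admits pure noise", {
  set.seed(44)
  n <- 400
  picked_noise <- logical(200)
  for (rep_i in 1:200) {
    x_noise <- rnorm(n)
    t <- rexp(n, 0.03)
    d <- data.frame(OS_months = t, event = 1, x = x_noise)
    fit <- cox_model(d, covariates = "x", stepwise = TRUE)
    picked_noise[rep_i] <- "x" %in% fit$selected
  }
  expect_lte(mean(picked_noise), 0.10)

  # a strong true effect is selected alongside, noise left out
  set.seed(45)
  x_true <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.03 * exp(1.2 * x_true))
  d <- data.frame(OS_months = t, event = 1, x_true = x_true, x_noise = rnorm(n))
  fit <- cox_model(d, covariates = c("x_true", "x_noise"), stepwise = TRUE)
  expect_true("x_true" %in% fit$selected)
  expect_length(fit$trace, length(fit$selected))
})

test_that("LOO validation: separable risk gives concordance 1, noise about 0.5", {
  set.seed(46)
  d <- data.frame(OS_months = c(runif(25, 1, 10), runif(25, 50, 100)),
                  event = 1, x = rep(c(1, 0), each = 25))
  cv <- loo_cross_validate(d, covariates = "x")
  expect_equal(cv$concordance, 1)
  expect_equal(cv$completed, 1)

  cs <- sapply(1:6, function(s) {
    set.seed(100 + s)
    dn <- data.frame(OS_months = rexp(100, 0.02),
                     event = rbinom(100, 1, 0.75), x = rnorm(100))
    loo_cross_validate(dn, covariates = "x")$concordance
  })
  expect_lt(abs(mean(cs) - 0.5), 0.05)

  # determinism
  cv2 <- loo_cross_validate(d, covariates = "x")
  expect_identical(cv$linear_predictor, cv2$linear_predictor)
  expect_identical(cv$cv_partial_loglik, cv2$cv_partial_loglik)
})

test_that("exclusion arithmetic validates its inputs", {
  res <- cohort_exclusions(50, c(a = 3, b = 2))
  expect_equal(res$n_analyzed, 45L)
  expect_error(cohort_exclusions(4, c(a = 5)), "exceed")
})
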