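test_that("Kaplan-Meier estimates match the product-limit formula", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_true(all(diff(km$surv) <= 0))

  expect_warning(flat <- km_estimate(c(1, 2, 3), c(0, 0, 0)), "censored")
  expect_true(all(flat$surv == 1))

  # duplicating every subject leaves the curve unchanged
  t1 <- c(2, 4, 4, 7, 9)
  e1 <- c(1, 0, 1, 1, 0)
  km1 <- km_estimate(t1, e1)
  km2 <- km_estimate(rep(t1, 2), rep(e1, 2))
  expect_equal(km1$surv, km2$surv, tolerance = 1e-12)

  # with no censoring the KM curve is 1 - ECDF at event times
  set.seed(22)
  tt <- rexp(40)
  km3 <- km_estimate(tt, rep(1, 40))
  expect_equal(km3$surv, 1 - ecdf(tt)(km3$time), tolerance = 1e-12)
})

test_that("log-rank statistics match the hand-computed O/E/V toy", {
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr$observed[["A"]], 2)
  expect_equal(lr$expected[["A"]], 5 / 6, tolerance = 1e-4)
  expect_equal(lr$variance, 0.4722, tolerance = 1e-3)
  expect_equal(lr$chi_square, 2.882, tolerance = 1e-3)
  expect_equal(sum(lr$observed - lr$expected), 0, tolerance = 1e-9)

  # identical groups: no signal
  t0 <- c(1, 2, 3, 1, 2, 3)
  lr0 <- logrank_test(t0, rep(1, 6), rep(c("A", "B"), each = 3))
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  # label swap leaves the statistic unchanged
  set.seed(23)
  tt <- rexp(40); ev <- rbinom(40, 1, 0.7); gr <- rep(c("A", "B"), 20)
  swapped <- ifelse(gr == "A", "B", "A")
  expect_equal(logrank_test(tt, ev, gr)$chi_square,
               logrank_test(tt, ev, swapped)$chi_square, tolerance = 1e-12)
  expect_error(logrank_test(tt, ev, rep("A", 40)), "2 non-empty groups")
})

test_that("mean stratification applies the tie-to-low rule", {
  expect_identical(as.character(stratify_by_mean(c(1, 2, 3))),
                   c("low", "low", "high"))
  expect_warning(lab <- stratify_by_mean(rep(2, 5)), "constant")
  expect_true(all(lab == "low"))
  v <- c(0.5, 1.5, 4)
  expect_identical(stratify_by_mean(v), stratify_by_mean(v + 100))
  expect_error(stratify_by_mean(1), ">= 2 samples")
})

test_that("Cox fits maximize the Breslow partial likelihood", {
  tm <- c(2, 4, 5, 7, 9, 12)
  ev <- c(1, 1, 0, 1, 1, 0)
  x <- c(1, 0, 1, 0, 1, 0)
  fit <- cox_fit(tm, ev, data.frame(x = x))
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, breslow_loglik, numeric(1), time = tm, event = ev, x = x)
  expect_equal(fit$table$beta, grid[which.max(ll)], tolerance = 1e-3)
  expect_equal(fit$loglik, max(ll), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_lt(fit$table$ci_lower, fit$table$hr)
  expect_gt(fit$table$ci_upper, fit$table$hr)
})

test_that("null covariates give hazard ratios near one", {
  set.seed(24)
  cover <- vapply(1:20, function(i) {
    n <- 150
    tt <- rexp(n, 0.05)
    cc <- rexp(n, 0.02)
    x <- rnorm(n)
    fit <- cox_fit(pmin(tt, cc), as.integer(tt <= cc), data.frame(x = x))
    fit$table$ci_lower <= 1 && 1 <= fit$table$ci_upper
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("the planted mesenchymal hazard ratio is recovered", {
  co <- simulate_cohort(simulation_config(n_samples = 2000, n_genes = 50,
                                          n_mirnas = 10, regulon_size = 25,
                                          signature_size = 10,
                                          signature_regulon_overlap = 0.4,
                                          n_classifier_genes_planted = 5,
                                          seed = 25))
  mes <- mes_mask_of(co)
  uni <- cox_fit(co$samples$time, co$samples$event,
                 data.frame(mesenchymal = as.numeric(mes)))
  expect_gte(uni$table$hr, 2 * 0.7)
  expect_lte(uni$table$hr, 2 * 1.3)
  multi <- cox_fit(co$samples$time, co$samples$event,
                   data.frame(mesenchymal = as.numeric(mes),
                              age = co$samples$age, stage = co$samples$stage,
                              grade = co$samples$grade))
  hr_m <- multi$table$hr[multi$table$term == "mesenchymal"]
  expect_gte(hr_m, 2 * 0.7)
  expect_lte(hr_m, 2 * 1.3)
})

test_that("degenerate Cox inputs are rejected or flagged", {
  expect_error(cox_fit(c(1, 2, 3), c(0, 0, 0), data.frame(x = 1:3)),
               "at least one event")
  expect_error(cox_fit(c(1, 2, 3), c(1, 1, 0), data.frame(x = rep(2, 3))),
               "constant covariate")
  # perfectly separating covariate: monotone likelihood
  tm <- c(1, 2, 3, 10, 11, 12)
  ev <- rep(1, 6)
  x <- c(1, 1, 1, 0, 0, 0)
  fit <- suppressWarnings(cox_fit(tm, ev, data.frame(x = x)))
  if (!fit$converged) expect_true(is.na(fit$table$hr))
})
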