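test_that("log2 fold change is the mean difference and antisymmetric", {
  expect_equal(log2_fold_change(c(2, 3, 4), c(0, 1, 2)), 2)
  expect_equal(log2_fold_change(c(1, 2), c(1, 2)), 0)
  set.seed(1)
  a <- rnorm(10); b <- rnorm(12)
  expect_equal(log2_fold_change(a, b), -log2_fold_change(b, a))
  expect_error(log2_fold_change(numeric(0), 1), "non-empty")
})

test_that("welch test matches the closed-form statistic and handles degeneracy", {
  x <- c(1, 2, 3, 4)
  expect_equal(welch_t_test(x, x), list(statistic = 0, p_value = 1))
  expect_warning(res <- welch_t_test(c(0, 0, 0), c(1, 1, 1)), "zero-variance")
  expect_equal(res$p_value, 0)

  set.seed(7)
  a <- rnorm(20, 1); b <- rnorm(20, 0.5, 2)
  got <- welch_t_test(a, b)
  # independent hand computation of the Welch statistic / Satterthwaite df
  se2 <- var(a) / 20 + var(b) / 20
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((var(a) / 20)^2 / 19 + (var(b) / 20)^2 / 19)
  expect_equal(got$statistic, tstat, tolerance = 1e-8)
  expect_equal(got$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-8)
})

test_that("wilcoxon exact path equals full labeling enumeration", {
  got <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(got$U, 4)  # all four (a, b) pairs have a < b
  expect_equal(got$p_value, 1 / 3, tolerance = 1e-12)

  set.seed(3)
  for (i in 1:15) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    x <- sample(seq_len(50), n1)   # tie-free integers
    y <- sample(setdiff(seq_len(50), x), n2)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, enum_wilcox_p(x, y),
                 tolerance = 1e-12)
  }
  # tied data falls back to the corrected normal approximation
  expect_equal(wilcoxon_rank_sum(c(1, 2, 2), c(1, 2, 2))$p_value, 1)
})

test_that("benjamini-hochberg equals the step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(1:10, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, stepup_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= 0 & adj <= 1))
    expect_equal(order(adj, p), order(p, adj))
  }
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("welch type-I error is nominal on null data", {
  set.seed(21)
  p <- vapply(1:5000, function(i) {
    welch_t_test(rnorm(15), rnorm(15))$p_value
  }, numeric(1))
  expect_gte(mean(p < 0.05), 0.04)
  expect_lte(mean(p < 0.05), 0.06)
})

test_that("differential expression tables flag the planted regulator", {
  hits <- vapply(1:20, function(s) {
    co <- simulate_cohort(simulation_config(n_genes = 20, n_mirnas = 40,
                                            n_samples = 200, regulon_size = 10,
                                            signature_size = 10,
                                            n_classifier_genes_planted = 2,
                                            signature_regulon_overlap = 0.5,
                                            seed = 100 + s))
    de <- differential_expression_table(co$mirna_expr, mes_mask_of(co))
    co$truth$master_regulator %in% select_features(de, "less_than", -0.5, 1e-4)
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("single-feature tables carry adj_p equal to p", {
  m <- matrix(rnorm(20), 1, 20,
              dimnames = list("g1", sprintf("s%d", 1:20)))
  de <- differential_expression_table(expression_matrix(m, "gene"),
                                      rep(c(TRUE, FALSE), 10))
  expect_equal(nrow(de), 1)
  expect_equal(de$adj_p, de$p_value)
  expect_error(
    differential_expression_table(expression_matrix(m, "gene"), rep(TRUE, 20)),
    "non-empty"
  )
})

test_that("feature selection applies both rules and is monotone in the FDR ceiling", {
  tbl <- data.frame(
    feature_id = c("a", "b", "c", "d", "e"),
    log2fc = c(0.3, -0.4, 0.1, 0.9, -0.2),
    statistic = 0, p_value = c(0.001, 0.02, 0.001, 0.01, 0.2),
    adj_p = c(0.005, 0.04, 0.005, 0.03, 0.5)
  )
  expect_setequal(select_features(tbl, "abs_greater_than", 0.25, 0.05),
                  c("a", "b", "d"))
  expect_setequal(select_features(tbl, "abs_greater_than", 0.35, 0.05),
                  c("b", "d"))
  expect_identical(select_features(tbl, "greater_than", 2, 0.05), character(0))
  loose <- select_features(tbl, "abs_greater_than", 0.25, 0.05)
  tight <- select_features(tbl, "abs_greater_than", 0.25, 0.01)
  expect_true(all(tight %in% loose))
  expect_error(select_features(tbl, "between", 0, 1), "unknown lfc rule")
})
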