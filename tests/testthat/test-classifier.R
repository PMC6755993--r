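test_that("rank AUC matches pair counting, trapezoidal ROC and pROC", {
  expect_equal(auc_mann_whitney(c(4, 5, 6, 1, 2, 3),
                                c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)), 1)
  expect_equal(auc_mann_whitney(c(2, 4, 1, 3), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  set.seed(4)
  v <- rnorm(40)
  lab <- rep(c(TRUE, FALSE), 20)
  expect_equal(auc_mann_whitney(v, lab), 1 - auc_mann_whitney(v, !lab))

  # trapezoidal ROC integration on tie-free data
  trapezoid_auc <- function(values, pos) {
    th <- sort(unique(values), decreasing = TRUE)
    tpr <- vapply(c(Inf, th), function(t) mean(values[pos] >= t), numeric(1))
    fpr <- vapply(c(Inf, th), function(t) mean(values[!pos] >= t), numeric(1))
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  expect_equal(auc_mann_whitney(v, lab), trapezoid_auc(v, lab), tolerance = 1e-12)
  skip_if_not_installed("pROC")
  proc_auc <- as.numeric(pROC::auc(pROC::roc(lab, v, quiet = TRUE,
                                             direction = "<")))
  expect_equal(auc_mann_whitney(v, lab), proc_auc, tolerance = 1e-12)
})

test_that("two-step selection recovers planted classifier genes", {
  co <- planted_cohort(11)
  mes <- mes_mask_of(co)
  sel <- two_step_feature_selection(znormalize(co$gene_expr), mes)
  expect_setequal(sel, co$truth$classifier_genes)

  # relaxing the AUC floor can only grow the survivor set
  cfg0 <- analysis_config(auc_min = 0)
  cfg0$n_classifier_genes <- 10000L
  sel0 <- two_step_feature_selection(znormalize(co$gene_expr), mes, cfg0)
  expect_true(all(sel %in% sel0))

  null_co <- simulate_cohort(null_simulation_config(
    n_genes = 100, n_mirnas = 10, n_samples = 100, regulon_size = 20,
    signature_size = 10, signature_regulon_overlap = 0.4,
    n_classifier_genes_planted = 5, seed = 2))
  expect_error(
    two_step_feature_selection(znormalize(null_co$gene_expr), mes_mask_of(null_co)),
    "relaxing"
  )
})

test_that("nearest shrunken centroids obey the shrinkage identities", {
  set.seed(12)
  m <- rbind(g1 = c(rnorm(5, -2, 0.3), rnorm(5, 2, 0.3)),
             g2 = rnorm(10, 0, 0.3))
  colnames(m) <- sprintf("s%d", 1:10)
  em <- expression_matrix(m, "gene")
  y <- rep(c("A", "B"), each = 5)

  fit0 <- train_nsc(em, y, delta_grid = 0, n_folds = 5, seed = 1)
  class_means <- cbind(A = rowMeans(m[, 1:5]), B = rowMeans(m[, 6:10]))
  expect_equal(unname(fit0$shrunk_centroids), unname(class_means),
               tolerance = 1e-12)

  big_delta <- max(abs(fit0$d)) + 1
  fit_max <- train_nsc(em, y, delta_grid = big_delta, n_folds = 5, seed = 1)
  expect_true(all(fit_max$dshrunk == 0))
  pred <- predict_nsc(fit_max, em)
  expect_true(all(pred$predicted == "A" | length(unique(pred$predicted)) == 1))

  fit <- train_nsc(em, y, n_folds = 5, seed = 1)
  expect_true(all(abs(fit$dshrunk) <= abs(fit$d) + 1e-12))
  expect_true(all(fit$dshrunk[abs(fit$d) <= fit$delta] == 0))
  expect_equal(sum(fit$priors), 1)
})

test_that("discriminant scores match direct evaluation on the 2-gene toy", {
  X <- t(matrix(c(0, 0, 0.2, -0.1, -0.2, 0.1, 2, 2, 1.8, 2.1, 2.2, 1.9),
                ncol = 2, byrow = TRUE))
  dimnames(X) <- list(c("g1", "g2"), sprintf("s%d", 1:6))
  em <- expression_matrix(X, "gene")
  y <- rep(c("A", "B"), each = 3)
  model <- train_nsc(em, y, delta_grid = 0, n_folds = 3, seed = 1)

  xstar <- matrix(c(0.1, 0.2), ncol = 1, dimnames = list(c("g1", "g2"), "new"))
  pred <- predict_nsc(model, expression_matrix(xstar, "gene"))
  disc <- vapply(1:2, function(k) {
    sum((xstar[, 1] - model$shrunk_centroids[, k])^2 / (model$s_i + model$s0)^2) -
      2 * log(model$priors[k])
  }, numeric(1))
  post <- exp(-disc / 2 + max(disc / 2))
  post <- post / sum(post)
  expect_equal(pred$posterior_A, post[1], tolerance = 1e-9)
  expect_equal(pred$posterior_B, post[2], tolerance = 1e-9)
  expect_equal(pred$predicted, "A")
})

test_that("posteriors sum to one and missing features are reported", {
  co <- planted_cohort(13)
  mes <- mes_mask_of(co)
  gz <- znormalize(co$gene_expr)
  genes <- two_step_feature_selection(gz, mes)
  model <- train_nsc(subset_expression(gz, features = genes),
                     ifelse(mes, "mesenchymal", "other"), seed = 3)
  pred <- predict_nsc(model, gz)
  expect_lt(max(abs(pred$posterior_mesenchymal + pred$posterior_other - 1)), 1e-9)
  expect_true(is.logical(pred$mesenchymal_call))
  dropped <- subset_expression(gz, features = setdiff(gz$feature_ids, genes[1]))
  expect_error(predict_nsc(model, dropped), genes[1])
})

test_that("held-out classification of the planted subtype is near-perfect", {
  co <- planted_cohort(14)
  mes <- mes_mask_of(co)
  n <- length(mes)
  set.seed(99)
  train_idx <- sort(sample.int(n, round(0.7 * n)))
  test_idx <- setdiff(seq_len(n), train_idx)
  train_ids <- co$gene_expr$sample_ids[train_idx]
  test_ids <- co$gene_expr$sample_ids[test_idx]

  # each split z-normalized per its own cohort
  train_z <- znormalize(subset_expression(co$gene_expr, samples = train_ids))
  test_z <- znormalize(subset_expression(co$gene_expr, samples = test_ids))
  genes <- two_step_feature_selection(train_z, mes[train_idx])
  model <- train_nsc(subset_expression(train_z, features = genes),
                     ifelse(mes[train_idx], "mesenchymal", "other"), seed = 5)
  pred <- predict_nsc(model, test_z)
  acc <- mean((pred$predicted == "mesenchymal") == mes[test_idx])
  expect_gte(acc, 0.95)
})

test_that("NSC models survive JSON serialization", {
  co <- planted_cohort(15)
  mes <- mes_mask_of(co)
  gz <- znormalize(co$gene_expr)
  genes <- two_step_feature_selection(gz, mes)
  model <- train_nsc(subset_expression(gz, features = genes),
                     ifelse(mes, "mesenchymal", "other"), seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  nsc_model_to_json(model, path)
  back <- nsc_model_from_json(path)
  p1 <- predict_nsc(model, gz)
  p2 <- predict_nsc(back, gz)
  expect_equal(p1$posterior_mesenchymal, p2$posterior_mesenchymal,
               tolerance = 1e-12)
})
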