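#' Mann-Whitney (rank) area under the ROC curve
#'
#' AUC of a single feature for separating positives from negatives:
#' the probability that a random positive exceeds a random negative, ties
#' counted one half; equals U / (n+ * n-) with U oriented as in
#' [wilcoxon_rank_sum()] applied to (negatives, positives).
#'
#' @param values Numeric vector of per-sample feature values.
#' @param positive_mask Logical vector: TRUE for the positive class.
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(values, positive_mask) {
  stopifnot(length(values) == length(positive_mask))
  n_pos <- sum(positive_mask)
  n_neg <- sum(!positive_mask)
  if (n_pos == 0 || n_neg == 0) stop_validation("both classes must be non-empty")
  r <- rank(values)
  u <- sum(r[positive_mask]) - n_pos * (n_pos + 1) / 2
  u / (n_pos * n_neg)
}

#' Two-step classifier gene selection
#'
#' Step 1 keeps genes differentially expressed between the subtype of
#' interest and the rest (log2 fold change above `de_lfc_classifier`,
#' BH-adjusted p below `de_fdr_classifier`). Step 2 keeps genes whose
#' single-gene ROC AUC for the subtype exceeds `auc_min`; if more than
#' `n_classifier_genes` survive, the top n by AUC are kept (ties broken by
#' absolute fold change, then lexicographic id).
#'
#' @param em A z-normalized [expression_matrix()].
#' @param mes_mask Logical vector: TRUE for the subtype of interest.
#' @param config An [analysis_config()].
#' @return Character vector of selected feature ids, ordered by decreasing
#'   AUC.
#' @export
two_step_feature_selection <- function(em, mes_mask, config = analysis_config()) {
  de <- differential_expression_table(em, mes_mask, test = "welch")
  step1 <- select_features(de, "greater_than",
                           config$de_lfc_classifier, config$de_fdr_classifier)
  if (!length(step1)) {
    stop_validation(paste0(
      "no gene passed the differential-expression filter ",
      "(log2fc > %g, adj_p < %g); consider relaxing the thresholds"),
      config$de_lfc_classifier, config$de_fdr_classifier)
  }
  auc <- vapply(step1, function(g) auc_mann_whitney(em$values[g, ], mes_mask),
                numeric(1))
  keep <- auc > config$auc_min
  if (!any(keep)) {
    stop_validation(paste0(
      "no gene passed the AUC filter (> %g); ",
      "consider relaxing auc_min"), config$auc_min)
  }
  ids <- step1[keep]
  auc <- auc[keep]
  lfc <- de$log2fc[match(ids, de$feature_id)]
  ord <- order(-auc, -abs(lfc), ids)
  ids <- ids[ord]
  if (length(ids) > config$n_classifier_genes) {
    ids <- ids[seq_len(config$n_classifier_genes)]
  }
  ids
}

# Fit nearest-shrunken-centroid parameters for one shrinkage value.
# X: features x samples (already standardized per cohort); y: factor.
fit_nsc_ <- function(X, y, delta) {
  classes <- levels(y)
  n <- ncol(X)
  nk <- table(y)
  xbar <- rowMeans(X)
  centroids <- vapply(classes,
                      function(k) rowMeans(X[, y == k, drop = FALSE]),
                      numeric(nrow(X)))
  # pooled within-class dispersion
  ss <- matrix(0, nrow(X), 1)
  for (k in classes) {
    Xk <- X[, y == k, drop = FALSE]
    ss <- ss + rowSums((Xk - centroids[, k])^2)
  }
  s_i <- sqrt(as.numeric(ss) / (n - length(classes)))
  s0 <- median(s_i)
  m_k <- sqrt(1 / as.numeric(nk) - 1 / n)
  names(m_k) <- classes
  d <- sweep(centroids - xbar, 1, s_i + s0, "/")
  d <- sweep(d, 2, m_k, "/")
  dshrunk <- sign(d) * pmax(abs(d) - delta, 0)
  shrunk_centroids <- xbar + sweep(sweep(dshrunk, 1, s_i + s0, "*"), 2, m_k, "*")
  list(classes = classes, xbar = xbar, centroids = centroids,
       shrunk_centroids = shrunk_centroids, d = d, dshrunk = dshrunk,
       s_i = s_i, s0 = s0, m_k = m_k, delta = delta,
       priors = as.numeric(nk) / n)
}

nsc_discriminant_ <- function(fit, X) {
  # delta_k(x) = sum_i (x_i - centroid'_ik)^2 / (s_i + s0)^2 - 2 log pi_k
  denom <- (fit$s_i + fit$s0)^2
  out <- vapply(seq_along(fit$classes), function(j) {
    colSums((X - fit$shrunk_centroids[, j])^2 / denom) - 2 * log(fit$priors[j])
  }, numeric(ncol(X)))
  matrix(out, nrow = ncol(X), ncol = length(fit$classes))
}

#' Train a nearest-shrunken-centroid (PAM) classifier
#'
#' Standardized class-centroid deviations
#' `d_ik = (xbar_ik - xbar_i) / (m_k * (s_i + s0))` with
#' `m_k = sqrt(1/n_k - 1/n)` are soft-thresholded by the shrinkage Delta,
#' giving sparse shrunken centroids. Delta is chosen from `delta_grid` by
#' stratified cross-validated accuracy, ties resolved toward the largest
#' Delta (sparsest model). Class priors are the empirical class frequencies.
#'
#' @param em An [expression_matrix()] restricted to the classifier features,
#'   z-normalized per its cohort.
#' @param labels Factor or character vector of class labels per sample
#'   (>= 2 classes, each with >= 2 samples).
#' @param delta_grid Candidate shrinkage values; default is 30 values from 0
#'   to the largest |d_ik|.
#' @param n_folds Cross-validation folds (stratified by class).
#' @param seed Seed for the fold assignment.
#' @return A list of class `nsc_model`.
#' @export
train_nsc <- function(em, labels, delta_grid = NULL, n_folds = 10, seed = 1L) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  y <- factor(labels)
  if (length(y) != ncol(em$values)) stop_validation("labels must cover all samples")
  if (nlevels(y) < 2) stop_validation("need >= 2 classes")
  if (any(table(y) < 2)) {
    stop_validation("every class needs >= 2 samples (got: %s)",
                    paste(sprintf("%s=%d", levels(y), table(y)), collapse = ", "))
  }
  X <- em$values
  full <- fit_nsc_(X, y, 0)
  if (is.null(delta_grid)) {
    delta_grid <- seq(0, max(abs(full$d)), length.out = 30)
  }
  cv_acc <- rep(NA_real_, length(delta_grid))
  folds <- with_seed_(seed, {
    f <- integer(length(y))
    for (k in levels(y)) {
      idx <- which(y == k)
      f[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    f
  })
  n_folds_eff <- length(unique(folds))
  for (d in seq_along(delta_grid)) {
    correct <- 0L
    for (fold in unique(folds)) {
      tr <- folds != fold
      if (nlevels(droplevels(y[tr])) < nlevels(y)) next
      fit <- fit_nsc_(X[, tr, drop = FALSE], droplevels(y[tr]), delta_grid[d])
      disc <- nsc_discriminant_(fit, X[, !tr, drop = FALSE])
      pred <- fit$classes[max.col(-disc, ties.method = "first")]
      correct <- correct + sum(pred == as.character(y[!tr]))
    }
    cv_acc[d] <- correct / length(y)
  }
  best <- max(cv_acc)
  delta <- max(delta_grid[cv_acc == best])  # sparsest among the best
  fit <- fit_nsc_(X, y, delta)
  structure(
    c(fit,
      list(feature_ids = em$feature_ids,
           cv = data.frame(delta = delta_grid, accuracy = cv_acc),
           n_folds = n_folds_eff, seed = seed)),
    class = "nsc_model"
  )
}

#' @export
print.nsc_model <- function(x, ...) {
  cat(sprintf("nsc_model: %d features, classes [%s], delta = %.3f\n",
              length(x$feature_ids), paste(x$classes, collapse = ", "),
              x$delta))
  invisible(x)
}

#' Classify samples with a nearest-shrunken-centroid model
#'
#' Computes the Gaussian-discriminant score for each class and converts it to
#' posterior probabilities `p_k = exp(-delta_k / 2) / sum_l exp(-delta_l / 2)`
#' (evaluated stably by subtracting the max). The new matrix must be
#' z-normalized across its own cohort before classification. The
#' `mesenchymal_call` flag is TRUE when the mesenchymal-class posterior
#' exceeds `posterior_threshold`.
#'
#' @param model An `nsc_model` from [train_nsc()].
#' @param em_new A z-normalized [expression_matrix()] containing all model
#'   features.
#' @param posterior_threshold Posterior cutoff for the subtype call.
#' @return A data.frame: `sample_id`, one `posterior_<class>` column per
#'   class, `predicted`, and (when a mesenchymal class exists)
#'   `mesenchymal_call`.
#' @export
predict_nsc <- function(model, em_new, posterior_threshold = 0.5) {
  stopifnot(inherits(model, "nsc_model"), inherits(em_new, "ExpressionMatrix"))
  missing <- setdiff(model$feature_ids, em_new$feature_ids)
  if (length(missing)) {
    stop_validation("model features absent from new matrix: %s",
                    paste(missing, collapse = ", "))
  }
  X <- em_new$values[model$feature_ids, , drop = FALSE]
  disc <- nsc_discriminant_(model, X)
  ll <- -disc / 2
  ll <- ll - apply(ll, 1, max)
  post <- exp(ll) / rowSums(exp(ll))
  colnames(post) <- model$classes
  out <- data.frame(sample_id = em_new$sample_ids, stringsAsFactors = FALSE)
  for (k in model$classes) out[[paste0("posterior_", k)]] <- post[, k]
  out$predicted <- model$classes[max.col(post, ties.method = "first")]
  if ("mesenchymal" %in% model$classes) {
    out$mesenchymal_call <- post[, "mesenchymal"] > posterior_threshold
  }
  out
}

#' Serialize / restore an NSC model as JSON
#'
#' @param model An `nsc_model`.
#' @param path Output (input) path.
#' @return `nsc_model_to_json` returns `path` invisibly;
#'   `nsc_model_from_json` returns the restored `nsc_model`.
#' @export
nsc_model_to_json <- function(model, path) {
  payload <- model[c("classes", "xbar", "centroids", "shrunk_centroids", "d",
                     "dshrunk", "s_i", "s0", "m_k", "delta", "priors",
                     "feature_ids")]
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "columnmajor")
  invisible(path)
}

#' @rdname nsc_model_to_json
#' @export
nsc_model_from_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("centroids", "shrunk_centroids", "d", "dshrunk")) {
    # written column-major: each serialized inner array is one class column,
    # which simplifyVector lays out as a row
    m <- payload[[f]]
    if (!is.matrix(m)) m <- matrix(m, nrow = length(payload$classes))
    payload[[f]] <- matrix(t(m), ncol = length(payload$classes),
                           dimnames = list(payload$feature_ids, payload$classes))
  }
  payload$m_k <- setNames(as.numeric(payload$m_k), payload$classes)
  payload$xbar <- setNames(as.numeric(payload$xbar), payload$feature_ids)
  payload$s_i <- as.numeric(payload$s_i)
  structure(payload, class = "nsc_model")
}
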