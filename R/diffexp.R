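#' Log2 fold change between two groups
#'
#' On log2-scale input the fold change is simply `mean(x) - mean(y)`, the
#' group of interest minus the reference (here, mesenchymal minus
#' non-mesenchymal).
#'
#' @param x,y Numeric vectors (log2 expression) for the two groups.
#' @return A single number.
#' @export
log2_fold_change <- function(x, y) {
  if (!length(x) || !length(y)) stop_validation("both groups must be non-empty")
  mean(x) - mean(y)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test with Satterthwaite degrees of freedom. Degenerate
#' inputs follow a fixed convention: both groups constant with equal means
#' gives t = 0, p = 1; constant with different means gives p = 0 with a
#' warning.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return A list with `statistic` and `p_value` (two-sided).
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop_validation("welch_t_test needs >= 2 observations per group")
  }
  vx <- var(x)
  vy <- var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      return(list(statistic = 0, p_value = 1))
    }
    warning("zero-variance groups with different means: p = 0 by convention")
    return(list(statistic = sign(mean(x) - mean(y)) * Inf, p_value = 0))
  }
  ht <- t.test(x, y, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' U counts pairs (a, b) with a < b, a drawn from the first group (ties count
#' one half) -- the orientation that makes `U / (n1 * n2)` the ROC AUC of the
#' second group over the first. The p-value is exact (by enumeration of
#' labelings) when the groups are tie-free with at most 12 observations in
#' total, otherwise a normal approximation with tie and continuity correction
#' is used.
#'
#' @param x,y Numeric vectors for the two groups.
#' @return A list with `U` and `p_value` (two-sided).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop_validation("both groups must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  # rank-sum statistic for x counts pairs x > y (+ half-ties); flip it
  u_x_gt_y <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u <- n1 * n2 - u_x_gt_y
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- !has_ties && (n1 + n2) <= 12
  p <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
  list(U = u, p_value = p)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment `adj_(i) = min_(j >= i) p_(j) * m / j`, clipped at 1 and
#' mapped back to the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_validation("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Per-feature two-group differential expression
#'
#' Tests every feature of an expression matrix between the group of interest
#' (mesenchymal) and the rest, reporting the log2 fold change
#' (mesenchymal minus rest), test statistic, p-value and BH-adjusted p-value
#' (adjusted jointly over all features of the matrix).
#'
#' @param em An [expression_matrix()].
#' @param mes_mask Logical vector over samples: TRUE for the group of
#'   interest.
#' @param test `"welch"` (default) or `"wilcoxon"`.
#' @return A data.frame with columns `feature_id`, `log2fc`, `statistic`,
#'   `p_value`, `adj_p`, `test`.
#' @export
differential_expression_table <- function(em, mes_mask,
                                          test = c("welch", "wilcoxon")) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  test <- match.arg(test)
  if (length(mes_mask) != ncol(em$values)) {
    stop_validation("labels must cover all %d samples", ncol(em$values))
  }
  if (!any(mes_mask) || all(mes_mask)) {
    stop_validation("both classes must be non-empty")
  }
  a <- em$values[, mes_mask, drop = FALSE]
  b <- em$values[, !mes_mask, drop = FALSE]
  res <- lapply(seq_len(nrow(em$values)), function(i) {
    x <- a[i, ]
    y <- b[i, ]
    if (test == "welch") {
      ht <- welch_t_test(x, y)
      c(stat = ht$statistic, p = ht$p_value)
    } else {
      ht <- wilcoxon_rank_sum(x, y)
      c(stat = ht$U, p = ht$p_value)
    }
  })
  stat <- vapply(res, `[[`, numeric(1), "stat")
  p <- vapply(res, `[[`, numeric(1), "p")
  data.frame(
    feature_id = em$feature_ids,
    log2fc = rowMeans(a) - rowMeans(b),
    statistic = stat,
    p_value = p,
    adj_p = benjamini_hochberg(p),
    test = if (test == "welch") "welch_t" else "wilcoxon",
    stringsAsFactors = FALSE
  )
}

#' Filter a differential-expression table by fold change and FDR
#'
#' @param table Output of [differential_expression_table()].
#' @param lfc_rule One of `"less_than"`, `"greater_than"`,
#'   `"abs_greater_than"`, applied to `log2fc`.
#' @param lfc_threshold Threshold for the rule.
#' @param fdr_ceiling Upper bound on `adj_p`.
#' @return Character vector of qualifying feature ids (possibly empty).
#' @export
select_features <- function(table, lfc_rule, lfc_threshold, fdr_ceiling) {
  rules <- c("less_than", "greater_than", "abs_greater_than")
  if (!lfc_rule %in% rules) {
    stop_validation("unknown lfc rule '%s'; use one of %s", lfc_rule,
                    paste(rules, collapse = ", "))
  }
  pass_lfc <- switch(lfc_rule,
    less_than = table$log2fc < lfc_threshold,
    greater_than = table$log2fc > lfc_threshold,
    abs_greater_than = abs(table$log2fc) > lfc_threshold
  )
  table$feature_id[pass_lfc & table$adj_p < fdr_ceiling]
}
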