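#' Default number of equal-frequency bins
#'
#' `clamp(floor(sqrt(n / 5)), 2, 10)`: grows slowly with the sample count so
#' each cell of the contingency table keeps a reasonable expected count.
#'
#' @param n Sample count.
#' @return Integer bin count.
#' @export
default_bins <- function(n) {
  max(2L, min(10L, as.integer(floor(sqrt(n / 5)))))
}

#' Equal-frequency (quantile) bin labels
#'
#' Assigns each value to one of `n_bins` bins of (near-)equal occupancy using
#' ranks; ties are broken by stable rank ordering (`ties.method = "first"`),
#' which makes the binning, and hence the MI estimate, exactly invariant
#' under strictly monotone transforms on tie-free data.
#'
#' @param x Numeric vector.
#' @param n_bins Number of bins.
#' @return Integer vector of bin labels in `1..n_bins`.
#' @export
bin_equal_freq <- function(x, n_bins) {
  n <- length(x)
  as.integer(ceiling(rank(x, ties.method = "first") * n_bins / n))
}

#' Plug-in mutual information with equal-frequency binning
#'
#' MI in nats on the `n_bins` x `n_bins` contingency table of quantile-binned
#' variables. A constant vector yields MI = 0 by convention.
#'
#' @param x,y Equal-length numeric vectors (n >= 20 recommended).
#' @param n_bins Bin count; defaults to [default_bins()] of the length.
#' @return Nonnegative MI in nats.
#' @export
mutual_information <- function(x, y, n_bins = NULL) {
  if (length(x) != length(y)) stop_validation("x and y must have equal length")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) return(0)
  if (is.null(n_bins)) n_bins <- default_bins(length(x))
  bx <- matrix(bin_equal_freq(x, n_bins), nrow = 1)
  by <- matrix(bin_equal_freq(y, n_bins), nrow = 1)
  mi_cross_cpp(bx, by, n_bins)[1, 1]
}

bin_matrix_ <- function(m, n_bins) {
  t(apply(m, 1, bin_equal_freq, n_bins = n_bins))
}

perm_matrix_ <- function(n, n_perm) {
  t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
}

#' Permutation p-values for all regulator-target MI pairs
#'
#' For each regulator, its sample order is permuted `n_permutations` times
#' and the MI against every target recomputed; the permutation p-value is
#' `(1 + #{MI_perm >= MI_obs}) / (1 + n_permutations)` and is BH-adjusted
#' over all pairs jointly.
#'
#' @param reg_em,tgt_em Z-normalized [expression_matrix()] objects sharing
#'   sample order (regulators, targets).
#' @param n_bins Bin count; default [default_bins()].
#' @param n_permutations Number of permutations (>= 100).
#' @param seed RNG seed; the same seed yields bit-identical p-values.
#' @return A data.frame with one row per pair: `regulator`, `target`, `mi`,
#'   `perm_p`, `adj_p`.
#' @export
permutation_pvalues <- function(reg_em, tgt_em, n_bins = NULL,
                                n_permutations = 1000, seed = 1L) {
  stopifnot(inherits(reg_em, "ExpressionMatrix"), inherits(tgt_em, "ExpressionMatrix"))
  if (n_permutations < 100) stop_validation("need n_permutations >= 100")
  n <- ncol(reg_em$values)
  if (ncol(tgt_em$values) != n) stop_validation("matrices must share samples")
  if (is.null(n_bins)) n_bins <- default_bins(n)
  reg_bins <- bin_matrix_(reg_em$values, n_bins)
  tgt_bins <- bin_matrix_(tgt_em$values, n_bins)
  mi_obs <- mi_cross_cpp(reg_bins, tgt_bins, n_bins)
  counts <- with_seed_(seed, {
    t(vapply(seq_len(nrow(reg_bins)), function(r) {
      perms <- perm_matrix_(n, n_permutations)
      as.integer(mi_perm_counts_cpp(reg_bins[r, ], tgt_bins, n_bins, perms,
                                    mi_obs[r, ]))
    }, integer(nrow(tgt_bins))))
  })
  perm_p <- (1 + counts) / (1 + n_permutations)
  out <- data.frame(
    regulator = rep(reg_em$feature_ids, times = nrow(tgt_bins)),
    target = rep(tgt_em$feature_ids, each = nrow(reg_bins)),
    mi = as.vector(mi_obs),
    perm_p = as.vector(perm_p),
    stringsAsFactors = FALSE
  )
  out$adj_p <- benjamini_hochberg(out$perm_p)
  out
}

#' Bootstrap consensus support for significant pairs
#'
#' Samples are resampled with replacement `n_bootstraps` times; within each
#' resample the variables are re-binned, the pair MI recomputed, and compared
#' against that resample's significance cutoff: the `(1 - alpha)` quantile of
#' a per-regulator permutation null (`n_null_perms` regulator permutations,
#' pooled over that regulator's tested targets). Support is the fraction of
#' resamples in which the pair's MI exceeds the cutoff.
#'
#' @param reg_em,tgt_em Z-normalized [expression_matrix()] objects.
#' @param pairs Data.frame with `regulator` and `target` columns (the
#'   significant pairs to score).
#' @param n_bins Bin count; default [default_bins()].
#' @param n_bootstraps Number of bootstrap resamples (>= 10).
#' @param alpha Significance level defining the per-resample cutoff.
#' @param n_null_perms Permutations used for the per-resample null.
#' @param seed RNG seed.
#' @return `pairs` with an added `support` column in \[0, 1\].
#' @export
bootstrap_support <- function(reg_em, tgt_em, pairs, n_bins = NULL,
                              n_bootstraps = 100, alpha = 0.05,
                              n_null_perms = 100, seed = 1L) {
  stopifnot(inherits(reg_em, "ExpressionMatrix"), inherits(tgt_em, "ExpressionMatrix"))
  if (n_bootstraps < 10) stop_validation("need n_bootstraps >= 10")
  n <- ncol(reg_em$values)
  if (is.null(n_bins)) n_bins <- default_bins(n)
  pairs <- pairs[, c("regulator", "target")]
  if (!nrow(pairs)) {
    pairs$support <- numeric(0)
    return(pairs)
  }
  by_reg <- split(pairs$target, pairs$regulator)
  hits <- matrix(0L, nrow = nrow(pairs), ncol = 1)
  key <- paste0(pairs$regulator, "\r", pairs$target)
  with_seed_(seed, {
    for (b in seq_len(n_bootstraps)) {
      idx <- sample.int(n, replace = TRUE)
      for (r in names(by_reg)) {
        tgts <- by_reg[[r]]
        rb <- matrix(bin_equal_freq(reg_em$values[r, idx], n_bins), nrow = 1)
        tb <- bin_matrix_(tgt_em$values[tgts, idx, drop = FALSE], n_bins)
        mi_b <- mi_cross_cpp(rb, tb, n_bins)[1, ]
        perms <- perm_matrix_(n, n_null_perms)
        null_mi <- mi_perm_matrix_cpp(rb[1, ], tb, n_bins, perms)
        cutoff <- quantile(as.vector(null_mi), 1 - alpha, names = FALSE)
        ok <- mi_b > cutoff
        rows <- match(paste0(r, "\r", tgts), key)
        hits[rows] <- hits[rows] + as.integer(ok)
      }
    }
  })
  pairs$support <- as.numeric(hits) / n_bootstraps
  pairs
}
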