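#' Rank genes by mesenchymal log2 fold change
#'
#' Builds the preranked input for GSEA: the phenotype is the log2 fold change
#' between subtype-of-interest and other samples, ordered descending with
#' deterministic lexicographic tie-break.
#'
#' @param em An [expression_matrix()].
#' @param mes_mask Logical vector: TRUE for subtype-of-interest samples.
#' @return A data.frame `id`, `score`, ordered by decreasing score.
#' @export
rank_by_log2fc <- function(em, mes_mask) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (!any(mes_mask) || all(mes_mask)) stop_validation("both classes must be non-empty")
  score <- rowMeans(em$values[, mes_mask, drop = FALSE]) -
    rowMeans(em$values[, !mes_mask, drop = FALSE])
  out <- data.frame(id = em$feature_ids, score = unname(score),
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$id), , drop = FALSE]
}

# ES of the weighted KS running sum given sorted hit positions.
# pos: sorted 1-based positions of set members in the ranked list;
# w: |score|^weight_p at those positions; N: list length.
# Returns es, the extremum hit index and its direction.
es_from_positions_ <- function(pos, w, N) {
  k <- length(pos)
  wsum <- sum(w)
  hit_cum <- if (wsum > 0) cumsum(w) / wsum else seq_len(k) / k
  n_miss <- N - k
  miss_step <- if (n_miss > 0) (pos - seq_len(k)) / n_miss else rep(0, k)
  after <- hit_cum - miss_step           # walk value just after each hit
  before <- c(0, hit_cum[-k]) - miss_step  # value just before each hit
  max_pos <- max(after, 0)
  min_neg <- min(before, 0)
  if (max_pos >= abs(min_neg)) {
    i <- which.max(after)
    list(es = max_pos, extremum = i, direction = 1L)
  } else {
    i <- which.min(before)
    list(es = min_neg, extremum = i, direction = -1L)
  }
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Running-sum statistic over a ranked gene list: hits advance by
#' `|score|^weight_p` (normalized over the set), misses retreat by
#' `1/(N - N_hit)`; the ES is the signed extremum of the walk. With
#' `weight_p = 0` this is the classical two-sample KS statistic between
#' member and non-member rank distributions. The leading edge contains the
#' members at or before the extremum (at or after it, for negative ES).
#'
#' @param ranked Data.frame `id`, `score` ordered by decreasing score (as
#'   from [rank_by_log2fc()]).
#' @param gene_set Character vector of member ids.
#' @param weight_p Weighting exponent (default 1, the tool's classic
#'   default).
#' @return A list with `es` and `leading_edge`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  hit <- ranked$id %in% gene_set
  if (!any(hit)) stop_validation("gene set does not intersect the ranked list")
  pos <- which(hit)
  w <- abs(ranked$score[pos])^weight_p
  res <- es_from_positions_(pos, w, nrow(ranked))
  leading <- if (res$direction > 0) {
    ranked$id[pos[seq_len(res$extremum)]]
  } else {
    ranked$id[pos[seq(res$extremum, length(pos))]]
  }
  list(es = res$es, leading_edge = leading)
}

#' Preranked GSEA with gene-permutation null
#'
#' For every gene set (filtered to `[min_size, max_size]` after intersection
#' with the ranked list) the enrichment score is computed, and a null
#' distribution is built by permuting gene labels (equivalently, drawing the
#' member positions uniformly without replacement) `n_permutations` times.
#' The nominal p is one-sided on the matching ES sign, NES is the ES divided
#' by the mean |null ES| of the same sign, and the FDR q follows the
#' positive/negative-pool convention of the original method.
#'
#' @param ranked Data.frame `id`, `score` ordered by decreasing score.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param n_permutations Permutations for the null (>= 100 recommended; a
#'   warning is emitted below that).
#' @param seed RNG seed.
#' @param weight_p Weighting exponent.
#' @param min_size,max_size Set-size bounds after intersection.
#' @return A data.frame with one row per retained set: `set_name`, `size`,
#'   `es`, `nes`, `nom_p`, `fdr_q`, `leading_edge` (comma-separated).
#' @export
gsea_run <- function(ranked, collection, n_permutations = 1000, seed = 1L,
                     weight_p = 1, min_size = 5, max_size = 500) {
  if (n_permutations < 100) warning("fewer than 100 permutations: p-values are coarse")
  ids <- ranked$id
  N <- length(ids)
  sizes <- vapply(collection, function(s) sum(ids %in% s), integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  skipped <- names(collection)[!keep]
  if (length(skipped)) {
    warning(sprintf("%d set(s) outside [%d, %d] after intersection skipped",
                    length(skipped), min_size, max_size))
  }
  collection <- collection[keep]
  if (!length(collection)) stop_validation("no gene set left after size filtering")

  abs_w <- abs(ranked$score)^weight_p
  obs <- lapply(collection, function(s) enrichment_score(ranked, s, weight_p))
  es <- vapply(obs, `[[`, numeric(1), "es")

  null_es <- with_seed_(seed, {
    lapply(names(collection), function(nm) {
      k <- sum(ids %in% collection[[nm]])
      vapply(seq_len(n_permutations), function(p) {
        pos <- sort.int(sample.int(N, k))
        es_from_positions_(pos, abs_w[pos], N)$es
      }, numeric(1))
    })
  })

  nom_p <- numeric(length(es))
  nes <- numeric(length(es))
  null_nes <- vector("list", length(es))
  for (i in seq_along(es)) {
    nul <- null_es[[i]]
    same <- if (es[i] >= 0) nul[nul >= 0] else nul[nul < 0]
    nom_p[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
    denom_pos <- mean(nul[nul >= 0])
    denom_neg <- mean(abs(nul[nul < 0]))
    nes[i] <- if (es[i] >= 0) es[i] / denom_pos else es[i] / denom_neg
    nn <- ifelse(nul >= 0, nul / denom_pos, nul / denom_neg)
    null_nes[[i]] <- nn[is.finite(nn)]
  }

  pool <- unlist(null_nes)
  fdr_q <- vapply(seq_along(nes), function(i) {
    v <- nes[i]
    if (!is.finite(v)) return(NA_real_)
    if (v >= 0) {
      num <- sum(pool >= v) / max(1, sum(pool >= 0))
      den <- sum(nes >= v & is.finite(nes)) / max(1, sum(nes >= 0 & is.finite(nes)))
    } else {
      num <- sum(pool <= v) / max(1, sum(pool < 0))
      den <- sum(nes <= v & is.finite(nes)) / max(1, sum(nes < 0 & is.finite(nes)))
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))

  data.frame(
    set_name = names(collection),
    size = vapply(collection, function(s) sum(ids %in% s), integer(1)),
    es = es,
    nes = nes,
    nom_p = nom_p,
    fdr_q = fdr_q,
    leading_edge = vapply(obs, function(o) paste(o$leading_edge, collapse = ","),
                          character(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
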