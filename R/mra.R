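#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` that contains `K` signature genes, the probability of
#' seeing `k` or more signature genes. Evaluated via the stable log-space
#' tail of the hypergeometric distribution.
#'
#' @param N Universe size.
#' @param K Signature genes in the universe.
#' @param n Regulon size (draw).
#' @param k Observed overlap.
#' @return Probability in (0, 1\].
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) %% 1 != 0) || k < 0 || K > N || n > N || k > min(K, n)) {
    stop_validation("inconsistent hypergeometric arguments (N=%s K=%s n=%s k=%s)",
                    N, K, n, k)
  }
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Master-regulator analysis by regulon-signature overrepresentation
#'
#' Tests every regulon for overrepresentation of signature genes with an
#' upper-tail hypergeometric test, conditioning on the analysis universe (the
#' candidate-target gene set that entered network inference). Regulons and
#' the signature are intersected with the universe before counting; signature
#' genes absent from the universe are dropped with a message. BH correction
#' is applied across all regulators tested, and the coverage `proportion` is
#' the fraction k/K of (in-universe) signature genes inside the regulon.
#'
#' @param regulons Named list of regulons: character vectors of target ids,
#'   or data.frames with a `target` column (as from [regulons()]).
#' @param signature Character vector of signature gene ids.
#' @param universe Character vector: the analysis universe.
#' @return A data.frame with one row per regulator: `regulator`, `N`, `K`,
#'   `n`, `k`, `p_value`, `adj_p`, `proportion`.
#' @export
mra_enrichment <- function(regulons, signature, universe) {
  if (!length(universe)) stop_validation("empty universe")
  universe <- unique(universe)
  sig_u <- intersect(signature, universe)
  dropped <- length(setdiff(signature, universe))
  if (dropped) {
    message(sprintf("%d signature gene(s) outside the universe dropped", dropped))
  }
  if (!length(sig_u)) stop_validation("signature does not intersect the universe")
  if (!length(regulons)) stop_validation("no regulons supplied")
  targets_of <- function(r) {
    if (is.data.frame(r)) unique(r$target) else unique(as.character(r))
  }
  rows <- lapply(names(regulons), function(nm) {
    reg_u <- intersect(targets_of(regulons[[nm]]), universe)
    k <- length(intersect(reg_u, sig_u))
    data.frame(regulator = nm, N = length(universe), K = length(sig_u),
               n = length(reg_u), k = k,
               p_value = hypergeometric_tail(length(universe), length(sig_u),
                                             length(reg_u), k),
               proportion = k / length(sig_u),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- benjamini_hochberg(out$p_value)
  out[, c("regulator", "N", "K", "n", "k", "p_value", "adj_p", "proportion")]
}

#' Rank master-regulator candidates
#'
#' Sorts by adjusted p ascending, breaking ties by signature coverage
#' (descending) and regulator id, and adds the `-log10(adj_p)` column used
#' for significance-vs-coverage plots.
#'
#' @param results Output of [mra_enrichment()].
#' @return The ranked data.frame with an added `neg_log10_adj_p` column.
#' @export
rank_master_regulators <- function(results) {
  if (!nrow(results)) stop_validation("no MRA results to rank")
  ord <- order(results$adj_p, -results$proportion, results$regulator)
  out <- results[ord, , drop = FALSE]
  out$neg_log10_adj_p <- -log10(out$adj_p)
  rownames(out) <- NULL
  out
}
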