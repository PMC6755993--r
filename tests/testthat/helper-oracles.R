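# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, closed forms, direct
# formula evaluation.

# Two-sided Mann-Whitney p by full enumeration of all C(n1+n2, n1) labelings,
# doubling the smaller tail of the U distribution (clipped at 1).
enum_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  combs <- utils::combn(length(pooled), n1)
  u_of <- function(a, b) sum(outer(a, b, "<")) + 0.5 * sum(outer(a, b, "=="))
  us <- apply(combs, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  u <- u_of(x, y)
  min(1, 2 * min(mean(us <= u), mean(us >= u)))
}

# BH by the literal step-up definition: adj_(i) = min_{j>=i} p_(j) * m / j.
stepup_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  pmin(1, adj_sorted)[order(ord)]
}

# Upper-tail hypergeometric by enumerating all C(N, n) draws.
enum_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)  # items 1..K are the "signature"
  mean(overlaps >= k)
}

# Classical signed two-sample KS statistic between member and non-member
# rank distributions (the weight-0 enrichment score). On an exact magnitude
# tie the positive extremum is reported, matching the ES convention.
ks_signed <- function(N, member_pos) {
  inside <- seq_len(N) %in% member_pos
  f_in <- cumsum(inside) / sum(inside)
  f_out <- cumsum(!inside) / sum(!inside)
  d <- f_in - f_out
  if (max(d) >= -min(d)) max(d) else min(d)
}

# Log partial likelihood with Breslow tie handling, for grid-search oracles.
breslow_loglik <- function(beta, time, event, x) {
  eta <- as.numeric(as.matrix(x) %*% beta)
  ll <- 0
  for (tt in unique(time[event == 1])) {
    d <- which(time == tt & event == 1)
    risk <- time >= tt
    ll <- ll + sum(eta[d]) - length(d) * log(sum(exp(eta[risk])))
  }
  ll
}

# Reduced-scale planted cohort used throughout the recovery tests.
planted_cohort <- function(seed) {
  simulate_cohort(reduced_simulation_config(seed = seed))
}

mes_mask_of <- function(cohort) cohort$samples$subtype == "mesenchymal"

edge_key <- function(df) paste(df$regulator, df$target, sep = ":")

random_gene_sets <- function(ids, n_sets, size, seed) {
  sets <- lapply(seq_len(n_sets), function(i) {
    set.seed(seed * 1000 + i)
    sample(ids, size)
  })
  names(sets) <- sprintf("random%02d", seq_len(n_sets))
  sets
}
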