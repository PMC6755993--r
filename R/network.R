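#' Data-processing-inequality pruning
#'
#' For every triangle formed by two regulator-target edges (R1-T, R2-T) and
#' the regulator-regulator association (R1-R2), the weakest of the three is
#' flagged when its MI falls below `(1 - tolerance)` times the smaller of the
#' other two, on the premise that an indirect dependency carries less
#' information than the direct paths composing it. Flagged regulator-target
#' edges are removed; regulator-regulator associations are used only for
#' adjudication and never enter the bipartite network.
#'
#' @param edges Data.frame of regulator-target edges with columns
#'   `regulator`, `target`, `mi`.
#' @param regreg Data.frame of regulator-regulator associations with columns
#'   `r1`, `r2`, `mi`.
#' @param tolerance DPI tolerance in \[0, 1\]; 0 is strict, 1 disables
#'   pruning.
#' @return `edges` with a logical `kept` column.
#' @export
dpi_filter <- function(edges, regreg, tolerance = 0) {
  stopifnot(tolerance >= 0, tolerance <= 1)
  kept <- rep(TRUE, nrow(edges))
  if (!nrow(edges) || !nrow(regreg)) {
    edges$kept <- kept
    return(edges)
  }
  rr_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  rr_mi <- setNames(regreg$mi, rr_key(regreg$r1, regreg$r2))
  edge_idx <- split(seq_len(nrow(edges)), edges$target)
  for (idx in edge_idx) {
    if (length(idx) < 2) next
    regs <- edges$regulator[idx]
    mis <- edges$mi[idx]
    for (a in seq_len(length(idx) - 1)) {
      for (b in seq(a + 1, length(idx))) {
        mi_rr <- rr_mi[rr_key(regs[a], regs[b])]
        if (is.na(mi_rr)) next
        tri <- c(mis[a], mis[b], mi_rr)
        w <- which.min(tri)
        if (tri[w] < (1 - tolerance) * min(tri[-w])) {
          if (w == 1) kept[idx[a]] <- FALSE
          if (w == 2) kept[idx[b]] <- FALSE
          # w == 3: the regulator-regulator association is weakest; it is not
          # part of the bipartite network, so nothing is removed
        }
      }
    }
  }
  edges$kept <- kept
  edges
}

#' Assign regulation signs to network edges
#'
#' Sign of the rank (Spearman) correlation between regulator and target
#' across paired samples: +1 induction, -1 repression. Pearson is available
#' as an option. Edges with exactly zero correlation have no defined sign and
#' are dropped with a warning.
#'
#' @param edges Data.frame with `regulator` and `target` columns.
#' @param mirna_expr,gene_expr [expression_matrix()] objects with shared
#'   sample order.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return `edges` with an integer `sign` column; zero-correlation edges
#'   removed.
#' @export
assign_edge_signs <- function(edges, mirna_expr, gene_expr,
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!nrow(edges)) {
    edges$sign <- integer(0)
    return(edges)
  }
  rho <- vapply(seq_len(nrow(edges)), function(i) {
    cor(mirna_expr$values[edges$regulator[i], ],
        gene_expr$values[edges$target[i], ], method = method)
  }, numeric(1))
  zero <- rho == 0 | is.na(rho)
  if (any(zero)) {
    warning(sprintf("%d edge(s) dropped: zero correlation, sign undefined", sum(zero)))
  }
  edges <- edges[!zero, , drop = FALSE]
  edges$sign <- as.integer(sign(rho[!zero]))
  edges
}

#' Infer a signed miRNA-to-gene regulatory network
#'
#' Full inference stage. Candidate regulators are miRNAs downregulated in
#' the subtype of interest (log2fc below `regulator_lfc_max`, BH-adjusted p
#' below `regulator_fdr`); candidate targets are genes differentially
#' expressed between the subtypes (absolute log2fc above
#' `target_abs_lfc_min`, BH-adjusted p below `target_fdr`). Both matrices
#' are independently z-normalized, then integrated: pairwise MI with
#' equal-frequency binning, per-regulator permutation p-values BH-filtered at
#' `target_fdr`, bootstrap consensus at `bootstrap_consensus`, DPI pruning at
#' `dpi_tolerance`, and Spearman sign assignment.
#'
#' @param gene_expr,mirna_expr Paired [expression_matrix()] objects with the
#'   same sample order.
#' @param mes_mask Logical vector: TRUE for subtype-of-interest samples.
#' @param config An [analysis_config()].
#' @param regulators,targets Optional explicit candidate id vectors that
#'   bypass the differential-expression selection.
#' @return A list of class `regulatory_network` with `edges` (all candidate
#'   pairs with `mi`, `perm_p`, `adj_p`, `support`, `sign`, `kept`),
#'   `regulators`, `targets` and a config echo.
#' @export
infer_network <- function(gene_expr, mirna_expr, mes_mask,
                          config = analysis_config(),
                          regulators = NULL, targets = NULL) {
  stopifnot(inherits(gene_expr, "ExpressionMatrix"),
            inherits(mirna_expr, "ExpressionMatrix"))
  if (!identical(gene_expr$sample_ids, mirna_expr$sample_ids)) {
    stop_validation("gene and miRNA matrices must share identical sample ids/order")
  }
  if (is.null(regulators)) {
    de_mir <- differential_expression_table(mirna_expr, mes_mask)
    regulators <- select_features(de_mir, "less_than",
                                  config$regulator_lfc_max, config$regulator_fdr)
  }
  if (is.null(targets)) {
    de_gene <- differential_expression_table(gene_expr, mes_mask)
    targets <- select_features(de_gene, "abs_greater_than",
                               config$target_abs_lfc_min, config$target_fdr)
  }
  if (!length(regulators)) {
    stop_validation("no candidate regulator passed the filters (log2fc < %g, adj_p < %g)",
                    config$regulator_lfc_max, config$regulator_fdr)
  }
  if (!length(targets)) {
    stop_validation("no candidate target passed the filters (|log2fc| > %g, adj_p < %g)",
                    config$target_abs_lfc_min, config$target_fdr)
  }
  targets <- setdiff(targets, regulators)

  reg_z <- znormalize(subset_expression(mirna_expr, features = regulators))
  tgt_z <- znormalize(subset_expression(gene_expr, features = targets))
  n <- ncol(reg_z$values)
  n_bins <- default_bins(n)

  edges <- permutation_pvalues(reg_z, tgt_z, n_bins = n_bins,
                               n_permutations = config$n_permutations,
                               seed = config$rng_seed + 101L)
  sig <- edges[edges$adj_p < config$target_fdr, , drop = FALSE]

  if (nrow(sig)) {
    supp <- bootstrap_support(reg_z, tgt_z, sig, n_bins = n_bins,
                              n_bootstraps = config$n_bootstraps,
                              alpha = config$target_fdr,
                              seed = config$rng_seed + 202L)
    sig$support <- supp$support[match(paste0(sig$regulator, "\r", sig$target),
                                      paste0(supp$regulator, "\r", supp$target))]
    sig <- sig[sig$support >= config$bootstrap_consensus, , drop = FALSE]
  } else {
    sig$support <- numeric(0)
  }

  # regulator-regulator MI, computed solely for DPI adjudication
  if (nrow(sig) && length(regulators) > 1) {
    reg_bins <- bin_matrix_(reg_z$values, n_bins)
    mi_rr <- mi_cross_cpp(reg_bins, reg_bins, n_bins)
    pairs <- which(upper.tri(mi_rr), arr.ind = TRUE)
    regreg <- data.frame(r1 = regulators[pairs[, 1]],
                         r2 = regulators[pairs[, 2]],
                         mi = mi_rr[pairs], stringsAsFactors = FALSE)
  } else {
    regreg <- data.frame(r1 = character(0), r2 = character(0), mi = numeric(0))
  }
  sig <- dpi_filter(sig, regreg, tolerance = config$dpi_tolerance)
  kept <- sig[sig$kept, , drop = FALSE]
  kept <- assign_edge_signs(kept, reg_z, tgt_z)

  edges$support <- kept$support[match(paste0(edges$regulator, "\r", edges$target),
                                      paste0(kept$regulator, "\r", kept$target))]
  edges$sign <- kept$sign[match(paste0(edges$regulator, "\r", edges$target),
                                paste0(kept$regulator, "\r", kept$target))]
  edges$kept <- !is.na(edges$sign)

  structure(
    list(edges = edges[order(edges$regulator, edges$target), ],
         regulators = regulators, targets = targets,
         n_bins = n_bins, config = config, seed = config$rng_seed),
    class = "regulatory_network"
  )
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d regulators x %d targets, %d kept edges\n",
              length(x$regulators), length(x$targets), sum(x$edges$kept)))
  invisible(x)
}

#' Kept edges of a network
#' @param network A `regulatory_network`.
#' @return Data.frame of kept edges.
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  network$edges[network$edges$kept, , drop = FALSE]
}

#' Extract regulons (signed target sets) from a network
#'
#' @param network A `regulatory_network` from [infer_network()].
#' @return A named list, one element per regulator with at least one kept
#'   edge: a data.frame of `target` and `sign`.
#' @export
regulons <- function(network) {
  kept <- network_edges(network)
  lapply(split(kept[, c("target", "sign")], kept$regulator), function(df) {
    rownames(df) <- NULL
    df
  })
}
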