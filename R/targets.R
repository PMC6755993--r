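#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation between paired observations; the two-sided p
#' comes from the t transform `r * sqrt((n - 2) / (1 - r^2))` with n - 2
#' degrees of freedom.
#'
#' @param x,y Paired numeric vectors (>= 3 finite values, nonzero variance).
#' @return A list with `r` and `p_value`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_validation("need >= 3 paired observations")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_validation("observations must be finite")
  }
  if (var(x) == 0 || var(y) == 0) stop_validation("zero variance in one argument")
  r <- cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p_value = 0))
  n <- length(x)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * pt(-abs(tstat), df = n - 2))
}

#' Triangulate direct-target candidates for one regulator
#'
#' Venn-style prioritization: the prioritized targets are the genes in the
#' regulator's inferred regulon AND the phenotype signature AND the
#' sequence-based predictions (by default the intersection of all supplied
#' prediction sources; `mode = "union"` requires membership in any source).
#' The full evidence table covers the union of all inputs and, when paired
#' expression is supplied, reports the Pearson correlation between the
#' regulator and each gene on the z-normalized cohort with BH correction
#' across the table.
#'
#' @param regulon Character vector of the regulator's inferred targets (or a
#'   data.frame with a `target` column, as from [regulons()]).
#' @param signature Character vector of signature gene ids.
#' @param predictions List of `target_predictions` objects (at least one).
#' @param regulator_id The regulator whose predictions to use; a source
#'   without this regulator contributes the empty set with a warning.
#' @param mirna_expr,gene_expr Optional paired [expression_matrix()] objects
#'   for the correlation columns.
#' @param mode `"intersection"` (default) or `"union"` over prediction
#'   sources.
#' @return A list with `prioritized` (character vector) and `evidence`
#'   (data.frame with membership flags and, when expression is given,
#'   `pearson_r`, `r_p_value`, `r_adj_p`).
#' @export
intersect_target_evidence <- function(regulon, signature, predictions,
                                      regulator_id,
                                      mirna_expr = NULL, gene_expr = NULL,
                                      mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  if (!length(predictions)) stop_validation("need at least one prediction source")
  if (is.data.frame(regulon)) regulon <- regulon$target
  regulon <- unique(as.character(regulon))
  signature <- unique(as.character(signature))
  per_source <- lapply(predictions, function(p) {
    src <- attr(p, "source_name")
    if (is.null(src)) src <- "prediction"
    if (!regulator_id %in% names(p)) {
      warning(sprintf("regulator %s absent from source '%s': contributes no genes",
                      regulator_id, src))
      character(0)
    } else {
      unique(p[[regulator_id]])
    }
  })
  seq_support <- Reduce(if (mode == "intersection") intersect else union, per_source)
  prioritized <- sort(intersect(intersect(regulon, signature), seq_support))

  all_genes <- sort(unique(c(regulon, signature, unlist(per_source))))
  evidence <- data.frame(
    gene_id = all_genes,
    in_regulon = all_genes %in% regulon,
    in_signature = all_genes %in% signature,
    in_seq_predictions = all_genes %in% seq_support,
    prioritized = all_genes %in% prioritized,
    stringsAsFactors = FALSE
  )
  if (!is.null(mirna_expr) && !is.null(gene_expr)) {
    if (!regulator_id %in% mirna_expr$feature_ids) {
      stop_validation("regulator %s absent from the miRNA matrix", regulator_id)
    }
    x <- as.numeric(znormalize(subset_expression(
      mirna_expr, features = regulator_id))$values)
    present <- evidence$gene_id %in% gene_expr$feature_ids
    gz <- znormalize(subset_expression(
      gene_expr, features = evidence$gene_id[present]))
    r <- rep(NA_real_, nrow(evidence))
    p <- rep(NA_real_, nrow(evidence))
    for (i in which(present)) {
      ct <- pearson_correlation(x, gz$values[evidence$gene_id[i], ])
      r[i] <- ct$r
      p[i] <- ct$p_value
    }
    evidence$pearson_r <- r
    evidence$r_p_value <- p
    evidence$r_adj_p <- NA_real_
    evidence$r_adj_p[present] <- benjamini_hochberg(p[present])
  }
  list(prioritized = prioritized, evidence = evidence)
}
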