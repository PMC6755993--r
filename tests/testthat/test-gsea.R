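make_ranked <- function(scores, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("g%03d", seq_along(scores))
  df <- data.frame(id = ids, score = scores, stringsAsFactors = FALSE)
  df[order(-df$score, df$id), ]
}

test_that("enrichment score walks match hand computation", {
  ranked <- make_ranked(c(4, 3, 2, 1))
  top <- enrichment_score(ranked, ranked$id[1], weight_p = 0)
  expect_equal(top$es, 1)
  expect_identical(top$leading_edge, ranked$id[1])
  bottom <- enrichment_score(ranked, ranked$id[4], weight_p = 0)
  expect_equal(bottom$es, -1)
  expect_identical(bottom$leading_edge, ranked$id[4])
  whole <- enrichment_score(ranked, ranked$id, weight_p = 0)
  expect_equal(whole$es, 1)
  expect_error(enrichment_score(ranked, "absent"), "does not intersect")
})

test_that("weight-0 ES equals the classical KS statistic", {
  set.seed(17)
  for (i in 1:25) {
    N <- sample(5:8, 1)
    k <- sample(1:(N - 1), 1)
    scores <- sort(rnorm(N), decreasing = TRUE)
    ranked <- make_ranked(scores)
    members <- sample(ranked$id, k)
    es <- enrichment_score(ranked, members, weight_p = 0)$es
    expect_equal(es, ks_signed(N, which(ranked$id %in% members)),
                 tolerance = 1e-12)
  }
})

test_that("weight-0 ES is invariant under increasing score transforms", {
  set.seed(18)
  scores <- rnorm(50)
  ranked <- make_ranked(scores)
  members <- sample(ranked$id, 8)
  base <- enrichment_score(ranked, members, weight_p = 0)$es
  warped <- make_ranked(exp(scores / 2), ids = sprintf("g%03d", seq_along(scores)))
  expect_equal(enrichment_score(warped, members, weight_p = 0)$es, base,
               tolerance = 1e-12)
})

test_that("gsea_run respects p-value bounds, filters and determinism", {
  set.seed(19)
  ranked <- make_ranked(rnorm(100))
  sets <- c(list(tiny = ranked$id[1:2]),
            random_gene_sets(ranked$id, 5, 15, seed = 3))
  expect_warning(res <- gsea_run(ranked, sets, n_permutations = 200, seed = 1),
                 "skipped")
  expect_false("tiny" %in% res$set_name)
  expect_true(all(res$nom_p >= 1 / 201))
  expect_true(all(abs(res$es) <= 1))
  res2 <- suppressWarnings(gsea_run(ranked, sets, n_permutations = 200, seed = 1))
  expect_identical(res, res2)
  expect_error(suppressWarnings(gsea_run(ranked, list(tiny = ranked$id[1:2]),
                                         n_permutations = 200, seed = 1)),
               "no gene set left")
})

test_that("weighted ES matches the fgsea implementation", {
  skip_if_not_installed("fgsea")
  set.seed(20)
  scores <- sort(rnorm(100), decreasing = TRUE)
  ranked <- make_ranked(scores)
  stats <- setNames(ranked$score, ranked$id)
  for (i in 1:5) {
    members <- sample(ranked$id, 12)
    es_pkg <- enrichment_score(ranked, members, weight_p = 1)$es
    es_fg <- fgsea::calcGseaStat(stats, which(ranked$id %in% members),
                                 gseaParam = 1)
    expect_equal(es_pkg, es_fg, tolerance = 1e-9)
  }
})

test_that("the planted signature outranks random size-matched sets", {
  co <- planted_cohort(42)
  mes <- mes_mask_of(co)
  ranked <- rank_by_log2fc(co$gene_expr, mes)
  sets <- c(list(signature = co$truth$signature),
            random_gene_sets(co$gene_expr$feature_ids, 20, 30, seed = 7))
  res <- gsea_run(ranked, sets, n_permutations = 500, seed = 2)
  best <- res$set_name[order(res$fdr_q, res$nom_p, -abs(res$nes))][1]
  expect_identical(best, "signature")
})

test_that("nominal p-values are calibrated on random scores and sets", {
  set.seed(21)
  frac <- vapply(1:10, function(s) {
    ranked <- make_ranked(rnorm(300))
    sets <- random_gene_sets(ranked$id, 20, 25, seed = 50 + s)
    res <- gsea_run(ranked, sets, n_permutations = 200, seed = s)
    mean(res$nom_p < 0.05)
  }, numeric(1))
  expect_lte(mean(frac), 0.08)
})
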