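test_that("DPI removes the weakest regulator-target edge of a triangle", {
  edges <- data.frame(regulator = c("R1", "R2"), target = c("T", "T"),
                      mi = c(0.9, 0.5))
  regreg <- data.frame(r1 = "R1", r2 = "R2", mi = 0.8)
  out <- dpi_filter(edges, regreg, tolerance = 0)
  expect_identical(out$kept, c(TRUE, FALSE))
  # full tolerance disables pruning
  out1 <- dpi_filter(edges, regreg, tolerance = 1)
  expect_true(all(out1$kept))
  # a weakest regulator-regulator association removes nothing bipartite
  regreg2 <- data.frame(r1 = "R1", r2 = "R2", mi = 0.2)
  out2 <- dpi_filter(edges, regreg2, tolerance = 0)
  expect_true(all(out2$kept))
})

test_that("the strongest edge of a triangle is never pruned", {
  set.seed(14)
  for (i in 1:25) {
    mis <- runif(3, 0.05, 1)
    edges <- data.frame(regulator = c("R1", "R2"), target = "T",
                        mi = mis[1:2])
    regreg <- data.frame(r1 = "R1", r2 = "R2", mi = mis[3])
    out <- dpi_filter(edges, regreg, tolerance = 0)
    strongest_rt <- which.max(mis[1:2])
    if (max(mis[1:2]) == max(mis)) {
      expect_true(out$kept[strongest_rt])
    }
  }
})

test_that("edge signs follow the direction of monotone association", {
  n <- 60
  x <- seq_len(n) + rnorm(n, 0, 0.01)
  m_reg <- matrix(x, 1, n, dimnames = list("r", sprintf("s%d", 1:n)))
  m_tgt <- rbind(up = 2 * x, down = -x^3)
  colnames(m_tgt) <- sprintf("s%d", 1:n)
  edges <- data.frame(regulator = c("r", "r"), target = c("up", "down"),
                      mi = 1)
  signed <- assign_edge_signs(edges, expression_matrix(m_reg, "mirna"),
                              expression_matrix(m_tgt, "gene"))
  expect_equal(signed$sign[signed$target == "up"], 1L)
  expect_equal(signed$sign[signed$target == "down"], -1L)
})

test_that("network inference is deterministic and calibrated on null cohorts", {
  co <- simulate_cohort(null_simulation_config(n_genes = 100, n_mirnas = 10,
                                               n_samples = 150,
                                               regulon_size = 20,
                                               signature_size = 10,
                                               signature_regulon_overlap = 0.4,
                                               n_classifier_genes_planted = 5,
                                               seed = 31))
  mes <- mes_mask_of(co)
  cfg <- analysis_config(rng_seed = 4, n_permutations = 500)
  net <- infer_network(co$gene_expr, co$mirna_expr, mes, cfg,
                       regulators = co$mirna_expr$feature_ids,
                       targets = co$gene_expr$feature_ids)
  expect_lte(sum(net$edges$kept) / nrow(net$edges), 0.05)
  net2 <- infer_network(co$gene_expr, co$mirna_expr, mes, cfg,
                        regulators = co$mirna_expr$feature_ids,
                        targets = co$gene_expr$feature_ids)
  expect_identical(net$edges, net2$edges)
})

test_that("planted edges are recovered with correct signs", {
  co <- planted_cohort(32)
  mes <- mes_mask_of(co)
  net <- infer_network(co$gene_expr, co$mirna_expr, mes,
                       analysis_config(rng_seed = 1))
  expect_setequal(net$regulators, co$truth$regulators)
  kept <- network_edges(net)
  truth <- truth_edge_list(co$truth)
  tp <- intersect(edge_key(kept), edge_key(truth))
  recall <- length(tp) / nrow(truth)
  expect_gte(recall, 0.8)
  merged <- merge(kept, truth, by = c("regulator", "target"))
  expect_gte(mean(merged$sign.x == merged$sign.y), 0.95)
  regs <- regulons(net)
  expect_true(all(unlist(lapply(regs, function(r) r$target)) %in% net$targets))
})

test_that("pipelines fail informatively when candidate sets are empty", {
  co <- simulate_cohort(null_simulation_config(n_genes = 50, n_mirnas = 10,
                                               n_samples = 100,
                                               regulon_size = 10,
                                               signature_size = 10,
                                               signature_regulon_overlap = 0.4,
                                               n_classifier_genes_planted = 5,
                                               seed = 33))
  mes <- mes_mask_of(co)
  expect_error(infer_network(co$gene_expr, co$mirna_expr, mes),
               "no candidate regulator")
})
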