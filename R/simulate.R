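#' Configuration for the synthetic paired cohort generator
#'
#' Defaults emulate a TCGA-like paired high-grade serous ovarian cancer
#' cohort: ~460 samples with both miRNA and mRNA profiles, a mesenchymal
#' fraction of 104/462, three subtype-downregulated miRNAs carrying planted
#' regulons (one master regulator whose regulon overlaps the phenotype
#' signature strongly, two decoys with low overlap), ten strongly
#' subtype-shifted classifier genes inside the master regulon, and
#' subtype-linked survival with independent censoring.
#'
#' @param n_samples Cohort size.
#' @param mesenchymal_fraction Probability a sample is mesenchymal.
#' @param n_genes,n_mirnas Feature counts.
#' @param n_planted_regulators Number of planted regulator miRNAs (the first
#'   is the master regulator).
#' @param regulon_size Targets per planted regulator.
#' @param signature_size Size of the phenotype (EMT-like) signature.
#' @param signature_regulon_overlap Fraction of the signature inside the
#'   master regulon.
#' @param decoy_signature_overlap Fraction of the signature inside each decoy
#'   regulon.
#' @param mirna_downshift Log2 downshift of planted miRNAs in mesenchymal
#'   samples.
#' @param coupling_strength Regression coefficient of a target gene on its
#'   regulator's centered expression.
#' @param repressed_fraction Fraction of regulon edges with sign -1
#'   (repression).
#' @param classifier_gene_shift Mesenchymal log2 shift of the planted
#'   classifier genes.
#' @param signature_shift Small mesenchymal log2 shift of non-classifier
#'   signature genes.
#' @param n_classifier_genes_planted Number of planted classifier genes
#'   (drawn from the master regulon, disjoint from the signature, on
#'   repressed edges).
#' @param noise_sd Gaussian noise standard deviation (log2 units) for both
#'   matrices.
#' @param baseline_hazard Event hazard per month for non-mesenchymal samples.
#' @param hr_mesenchymal Hazard ratio of mesenchymal vs non-mesenchymal.
#' @param censor_rate Independent exponential censoring hazard per month.
#' @param seed RNG seed; the same seed reproduces the cohort bit-identically.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 460,
                              mesenchymal_fraction = 104 / 462,
                              n_genes = 2000,
                              n_mirnas = 200,
                              n_planted_regulators = 3,
                              regulon_size = 80,
                              signature_size = 30,
                              signature_regulon_overlap = 0.6,
                              decoy_signature_overlap = 0.1,
                              mirna_downshift = 1.0,
                              coupling_strength = 0.8,
                              repressed_fraction = 0.9,
                              classifier_gene_shift = 1.5,
                              signature_shift = 0.2,
                              n_classifier_genes_planted = 10,
                              noise_sd = 0.5,
                              baseline_hazard = 0.02,
                              hr_mesenchymal = 2.0,
                              censor_rate = 0.015,
                              seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    mesenchymal_fraction = mesenchymal_fraction,
    n_genes = as.integer(n_genes),
    n_mirnas = as.integer(n_mirnas),
    n_planted_regulators = as.integer(n_planted_regulators),
    regulon_size = as.integer(regulon_size),
    signature_size = as.integer(signature_size),
    signature_regulon_overlap = signature_regulon_overlap,
    decoy_signature_overlap = decoy_signature_overlap,
    mirna_downshift = mirna_downshift,
    coupling_strength = coupling_strength,
    repressed_fraction = repressed_fraction,
    classifier_gene_shift = classifier_gene_shift,
    signature_shift = signature_shift,
    n_classifier_genes_planted = as.integer(n_classifier_genes_planted),
    noise_sd = noise_sd,
    baseline_hazard = baseline_hazard,
    hr_mesenchymal = hr_mesenchymal,
    censor_rate = censor_rate,
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(mesenchymal_fraction > 0, mesenchymal_fraction < 1,
              repressed_fraction >= 0, repressed_fraction <= 1,
              signature_regulon_overlap >= 0, signature_regulon_overlap <= 1,
              decoy_signature_overlap >= 0, decoy_signature_overlap <= 1,
              regulon_size < n_genes, signature_size <= n_genes,
              n_samples > 1, noise_sd > 0, baseline_hazard > 0,
              hr_mesenchymal > 0, censor_rate >= 0)
  })
  structure(cfg, class = "simulation_config")
}

#' Null-cohort configuration (no planted structure)
#'
#' Zeroes every planted effect (miRNA downshift, regulator-target coupling,
#' classifier/signature shifts, survival hazard ratio) so the generator emits
#' pure noise around per-feature baselines; used for type-I-error and
#' calibration checks.
#'
#' @param ... Overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
null_simulation_config <- function(...) {
  args <- list(...)
  defaults <- list(mirna_downshift = 0, coupling_strength = 0,
                   classifier_gene_shift = 0, signature_shift = 0,
                   hr_mesenchymal = 1)
  do.call(simulation_config, utils::modifyList(defaults, args))
}

#' Reduced-scale planted-cohort configuration
#'
#' The profile used for structure-recovery checks: 200 genes, 20 miRNAs and
#' 200 samples with a 40-gene regulon (the only non-default besides the
#' dimensions; the default 80-gene regulon cannot be scaled proportionally
#' because a regulon must hold at least the 18 signature genes it overlaps).
#'
#' @param seed RNG seed.
#' @param ... Further overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
reduced_simulation_config <- function(seed = 1L, ...) {
  simulation_config(n_genes = 200, n_mirnas = 20, n_samples = 200,
                    regulon_size = 40, seed = seed, ...)
}

#' Simulate a paired miRNA/mRNA cohort with planted ground truth
#'
#' Generative model, per sample s and feature baselines mu ~ N(7, 1) log2
#' units (microarray-like intensity scale):
#' \enumerate{
#'   \item subtype: mesenchymal with probability `mesenchymal_fraction`,
#'     otherwise one of the three non-mesenchymal subtypes at random;
#'   \item miRNA i: `x = mu_i - downshift * mes * planted(i) + N(0, sd^2)`;
#'   \item gene j in regulon(i):
#'     `y = mu_j + sign_ij * coupling * (x_i - mu_i) + gamma_j * mes + noise`,
#'     where `sign_ij = -1` for the repressed fraction of edges and `gamma_j`
#'     is `classifier_gene_shift` for planted classifier genes,
#'     `signature_shift` for other signature genes and 0 otherwise;
#'   \item non-target genes: baseline + gamma_j * mes + noise;
#'   \item survival: event time exponential with hazard
#'     `baseline_hazard * hr_mesenchymal^mes`, censored by an independent
#'     exponential at `censor_rate` plus an administrative cutoff at the 95th
#'     percentile of event times.
#' }
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_cohort` with elements `gene_expr`,
#'   `mirna_expr` (both [expression_matrix()]), `samples` (a `sample_table`)
#'   and `truth` (planted ground truth).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed_(config$seed, {
    n <- config$n_samples
    sample_ids <- sprintf("S%04d", seq_len(n))
    gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
    mirna_ids <- sprintf("MIR%03d", seq_len(config$n_mirnas))

    mes <- runif(n) < config$mesenchymal_fraction
    other <- setdiff(.subtype_levels, "mesenchymal")
    subtype <- ifelse(mes, "mesenchymal", sample(other, n, replace = TRUE))

    # planted structure ----------------------------------------------------
    regulators <- sample(mirna_ids, config$n_planted_regulators)
    master <- regulators[1]
    signature <- sample(gene_ids, config$signature_size)

    k_master <- round(config$signature_regulon_overlap * config$signature_size)
    k_decoy <- round(config$decoy_signature_overlap * config$signature_size)
    if (k_master > config$regulon_size) {
      stop_validation("generation error: master regulon (%d) smaller than its signature overlap (%d)",
                      config$regulon_size, k_master)
    }
    nonsig <- setdiff(gene_ids, signature)
    n_free_master <- config$regulon_size - k_master
    if (n_free_master < config$n_classifier_genes_planted) {
      stop_validation("generation error: master regulon has no room for %d classifier genes",
                      config$n_classifier_genes_planted)
    }
    regulons <- vector("list", length(regulators))
    names(regulons) <- regulators
    regulons[[master]] <- c(sample(signature, k_master),
                            sample(nonsig, n_free_master))
    for (r in setdiff(regulators, master)) {
      regulons[[r]] <- c(sample(signature, k_decoy),
                         sample(nonsig, config$regulon_size - k_decoy))
    }
    classifier_genes <- sample(setdiff(regulons[[master]], signature),
                               config$n_classifier_genes_planted)

    edges <- do.call(rbind, lapply(regulators, function(r) {
      tg <- regulons[[r]]
      sign <- ifelse(runif(length(tg)) < config$repressed_fraction, -1L, 1L)
      # classifier genes sit on repressed master edges: the master miRNA
      # represses the genes that mark the subtype
      sign[tg %in% classifier_genes] <- -1L
      data.frame(regulator = r, target = tg, sign = sign,
                 coupling = config$coupling_strength,
                 stringsAsFactors = FALSE)
    }))

    # per-gene subtype shift gamma
    gamma <- setNames(numeric(config$n_genes), gene_ids)
    gamma[intersect(signature, gene_ids)] <- config$signature_shift
    gamma[classifier_genes] <- config$classifier_gene_shift

    # expression ------------------------------------------------------------
    mu_mirna <- rnorm(config$n_mirnas, 7, 1)
    mu_gene <- rnorm(config$n_genes, 7, 1)
    names(mu_mirna) <- mirna_ids
    names(mu_gene) <- gene_ids

    mirna <- matrix(rnorm(config$n_mirnas * n, 0, config$noise_sd),
                    nrow = config$n_mirnas,
                    dimnames = list(mirna_ids, sample_ids))
    mirna <- mirna + mu_mirna
    mirna[regulators, mes] <- mirna[regulators, mes] - config$mirna_downshift

    genes <- matrix(rnorm(config$n_genes * n, 0, config$noise_sd),
                    nrow = config$n_genes,
                    dimnames = list(gene_ids, sample_ids))
    genes <- genes + mu_gene + outer(gamma, as.numeric(mes))
    for (i in seq_len(nrow(edges))) {
      r <- edges$regulator[i]
      tg <- edges$target[i]
      genes[tg, ] <- genes[tg, ] +
        edges$sign[i] * edges$coupling[i] * (mirna[r, ] - mu_mirna[r])
    }

    # survival --------------------------------------------------------------
    hazard <- config$baseline_hazard * ifelse(mes, config$hr_mesenchymal, 1)
    t_event <- rexp(n, rate = hazard)
    admin <- quantile(t_event, 0.95)
    t_cens <- if (config$censor_rate > 0) {
      pmin(rexp(n, rate = config$censor_rate), admin)
    } else {
      rep(admin, n)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    samples <- validate_sample_table(data.frame(
      sample_id = sample_ids,
      subtype = subtype,
      time = as.numeric(time),
      event = event,
      age = round(rnorm(n, 60, 10), 1),
      stage = sample(1:4, n, replace = TRUE, prob = c(0.05, 0.15, 0.6, 0.2)),
      grade = sample(1:3, n, replace = TRUE, prob = c(0.1, 0.45, 0.45)),
      stringsAsFactors = FALSE
    ))

    truth <- list(
      subtype = setNames(subtype, sample_ids),
      regulators = regulators,
      master_regulator = master,
      regulons = regulons,
      edges = edges,
      signature = signature,
      classifier_genes = classifier_genes,
      survival = list(baseline_hazard = config$baseline_hazard,
                      hr_mesenchymal = config$hr_mesenchymal,
                      censor_rate = config$censor_rate)
    )

    structure(
      list(gene_expr = expression_matrix(genes, "gene"),
           mirna_expr = expression_matrix(mirna, "mirna"),
           samples = samples,
           truth = truth,
           config = config),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d samples (%d mesenchymal), %d genes, %d miRNAs, %d planted regulators\n",
    nrow(x$samples), sum(x$samples$subtype == "mesenchymal"),
    nrow(x$gene_expr$values), nrow(x$mirna_expr$values),
    length(x$truth$regulators)))
  invisible(x)
}

#' Planted signed edge list from a cohort's ground truth
#'
#' @param truth The `truth` element of a [simulate_cohort()] result.
#' @return A data.frame with columns `regulator`, `target`, `sign`, one row
#'   per planted edge.
#' @export
truth_edge_list <- function(truth) {
  if (is.null(truth$edges)) stop_validation("ground truth carries no edge list")
  truth$edges[, c("regulator", "target", "sign")]
}
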