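# Synthetic expression data with full ground truth. Two generators mirror
# the two study designs the toolkit targets: a stem-cell differentiation
# experiment (3-level treatment, duplicate replicates per line, scan-date
# batches aligned with a global factor, Y-linked sex genes, a copy-number
# dosage block) and a lifespan brain series (non-linear age trajectories
# with a birth discontinuity, a continuous RNA-quality-like artifact).

#' Configuration for the stem-cell simulation
#'
#' Defaults emulate a differentiation experiment: `n_lines` cell lines, each
#' measured in duplicate under three conditions (undifferentiated,
#' mesendoderm, neurectoderm); a fraction of genes respond to one of the two
#' differentiated conditions with a log2 shift; Y-linked genes carry a large
#' male-only effect (8 log2 units, a >256-fold difference); a gene block
#' responds linearly to a 0/1/2 copy-number dosage; scan-date batches load a
#' shared latent factor onto a subset of genes, optionally confounded with
#' treatment; some lines fail to induce a small set of marker genes.
#'
#' Treatment-responsive genes split 60/20/20 into a shared differentiation
#' program (the same shift in both differentiated conditions — the dominant
#' axis, as in real differentiation series), a mesendoderm-specific program
#' and a neurectoderm-specific program. Realized batch levels are
#' standardized to the configured sd so the batch factor's magnitude is a
#' condition of the simulation, not a draw.
#'
#' @param n_lines Number of cell lines (default 10; half male).
#' @param replicates Replicates per line per condition (default 2).
#' @param n_genes Number of genes (default 2000).
#' @param treatment_frac Fraction of treatment-responsive genes (default 0.3).
#' @param treatment_effect Log2 shift magnitude of responsive genes (default 2).
#' @param n_y_genes Y-linked genes (default 10).
#' @param sex_effect Male-minus-female log2 shift on Y-linked genes (default 8).
#' @param n_cnv_genes Genes in the copy-number block (default 20).
#' @param cnv_probs Probabilities of 0, 1, 2 copies per line (default
#'   0.25/0.5/0.25).
#' @param cnv_effect Log2 shift per copy (default 3; 0 vs 2 copies spans 6 log2 units, emulating a presence/absence polymorphism).
#' @param n_batches Scan dates (default 5).
#' @param batch_sd Sd of the per-batch level of the shared batch factor
#'   (default 0.8).
#' @param batch_frac Fraction of genes loading on the batch factor (default 0.3).
#' @param confounding Degree of batch-treatment confounding in \[0, 1\]
#'   (0 = exactly balanced by stratified assignment; default 0).
#' @param noninducer_frac Fraction of lines failing to induce the marker
#'   genes (default 0.2).
#' @param n_marker_genes Marker genes subject to non-induction (default 5).
#' @param line_sd Sd of per-line, per-gene offsets (default 0.2).
#' @param noise_sd Residual noise sd (default 0.5).
#' @return A list of class `svclean_stemcell_config`.
#' @export
stemcell_config <- function(n_lines = 10, replicates = 2, n_genes = 2000,
                            treatment_frac = 0.3, treatment_effect = 2,
                            n_y_genes = 10, sex_effect = 8,
                            n_cnv_genes = 20, cnv_probs = c(0.25, 0.5, 0.25),
                            cnv_effect = 3,
                            n_batches = 5, batch_sd = 0.8, batch_frac = 0.3,
                            confounding = 0,
                            noninducer_frac = 0.2, n_marker_genes = 5,
                            line_sd = 0.2, noise_sd = 0.5) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$cnv_probs) - 1) > 1e-8) abort("`cnv_probs` must sum to 1.")
  if (cfg$confounding < 0 || cfg$confounding > 1) abort("`confounding` must be in [0, 1].")
  n_special <- ceiling(cfg$treatment_frac * cfg$n_genes) + cfg$n_y_genes + cfg$n_cnv_genes
  if (n_special > cfg$n_genes) abort("Effect-bearing gene counts exceed `n_genes`.")
  structure(cfg, class = "svclean_stemcell_config")
}

#' Simulate a stem-cell differentiation expression dataset
#'
#' Generates log2-scale expression as an additive per-gene model: baseline +
#' treatment shift + sex effect (Y-linked genes, male lines only) +
#' per-copy dosage effect (copy-number block) + batch-factor loading x batch
#' level + per-line offset + Gaussian noise. All injected structure is
#' recorded in the returned truth object, which suffices to reconstruct the
#' noise-free matrix exactly (see [reconstruct_signal()]).
#'
#' @param config From [stemcell_config()].
#' @param seed Required seed; the same seed reproduces the dataset exactly.
#' @return A list `(expr, samples, truth)`: the genes x samples matrix, the
#'   sample tibble (`sample_id`, `line`, `treatment`, `sex`, `cnv_dosage`,
#'   `scan_date`), and an `svclean_truth` object.
#' @export
simulate_stemcell <- function(config = stemcell_config(), seed = 1) {
  cfg <- config
  with_seed(seed, {
    conditions <- c("undifferentiated", "mesendoderm", "neurectoderm")
    samples <- tidyr::expand_grid(line = sprintf("line%02d", seq_len(cfg$n_lines)),
                                  treatment = conditions,
                                  rep = seq_len(cfg$replicates)) %>%
      dplyr::mutate(sample_id = paste(.data$line, substr(.data$treatment, 1, 3),
                                      .data$rep, sep = "_"))
    n <- nrow(samples)
    lines <- sprintf("line%02d", seq_len(cfg$n_lines))
    line_sex <- setNames(rep(c("male", "female"), length.out = cfg$n_lines), lines)
    line_cnv <- setNames(sample(0:2, cfg$n_lines, replace = TRUE, prob = cfg$cnv_probs),
                         lines)
    line_noninduce <- setNames(runif(cfg$n_lines) < cfg$noninducer_frac, lines)
    samples$sex <- unname(line_sex[samples$line])
    samples$cnv_dosage <- unname(line_cnv[samples$line])
    # scan-date batches: confounding 0 = stratified balance within condition
    # (batch exactly independent of treatment); confounding c sends a fraction
    # c of samples to a condition-linked batch instead
    cond_batch <- setNames(sample(seq_len(cfg$n_batches), 3, replace = cfg$n_batches < 3),
                           conditions)
    batch <- integer(n)
    for (cond in conditions) {
      idx <- which(samples$treatment == cond)
      batch[idx] <- sample(rep_len(seq_len(cfg$n_batches), length(idx)))
    }
    follow <- runif(n) < cfg$confounding
    batch[follow] <- cond_batch[samples$treatment[follow]]
    samples$scan_date <- sprintf("date%02d", batch)

    G <- cfg$n_genes
    gene_ids <- sprintf("g%05d", seq_len(G))
    n_treat <- ceiling(cfg$treatment_frac * G)
    idx_treat <- seq_len(n_treat)
    idx_y <- seq.int(n_treat + 1L, n_treat + cfg$n_y_genes)
    idx_cnv <- seq.int(n_treat + cfg$n_y_genes + 1L,
                       n_treat + cfg$n_y_genes + cfg$n_cnv_genes)

    baseline <- rnorm(G, mean = 8, sd = 1.5)
    delta_mes <- numeric(G); delta_nec <- numeric(G)
    # 60% shared differentiation program, 20% mesendoderm-, 20% neurectoderm-specific
    n_shared <- floor(0.6 * n_treat)
    n_mes <- floor(0.2 * n_treat)
    shared <- idx_treat[seq_len(n_shared)]
    mes_only <- idx_treat[seq.int(n_shared + 1L, n_shared + n_mes)]
    nec_only <- setdiff(idx_treat, c(shared, mes_only))
    sgn <- sample(c(-1, 1), G, TRUE) * cfg$treatment_effect
    delta_mes[shared] <- sgn[shared]; delta_nec[shared] <- sgn[shared]
    delta_mes[mes_only] <- sgn[mes_only]
    delta_nec[nec_only] <- sgn[nec_only]
    sex_eff <- numeric(G); sex_eff[idx_y] <- cfg$sex_effect
    cnv_eff <- numeric(G); cnv_eff[idx_cnv] <- cfg$cnv_effect
    batch_loading <- numeric(G)
    idx_batchgenes <- sample.int(G, ceiling(cfg$batch_frac * G))
    batch_loading[idx_batchgenes] <- rnorm(length(idx_batchgenes))
    bl <- rnorm(cfg$n_batches)
    batch_levels <- (bl - mean(bl)) / stats::sd(bl) * cfg$batch_sd
    line_effects <- matrix(rnorm(G * cfg$n_lines, sd = cfg$line_sd), G, cfg$n_lines,
                           dimnames = list(gene_ids, lines))
    # marker genes respond in neurectoderm only; non-inducer lines stay flat there
    marker_genes <- nec_only[seq_len(min(cfg$n_marker_genes, length(nec_only)))]
    delta_nec[marker_genes] <- cfg$treatment_effect

    gene_truth <- tibble::tibble(
      gene_id = gene_ids,
      delta_mes = delta_mes, delta_nec = delta_nec,
      sex_effect = sex_eff, cnv_effect = cnv_eff,
      batch_loading = batch_loading,
      is_marker = seq_len(G) %in% marker_genes)

    truth <- structure(list(gene_truth = gene_truth,
                            baseline = setNames(baseline, gene_ids),
                            line_effects = line_effects,
                            batch_levels = batch_levels,
                            sample_batch = batch,
                            noninducer = line_noninduce,
                            noise_sd = cfg$noise_sd,
                            kind = "stemcell",
                            seed = seed),
                       class = "svclean_truth")
    signal <- reconstruct_signal(truth, samples)
    expr <- signal + matrix(rnorm(G * n, sd = cfg$noise_sd), G, n)
    dimnames(expr) <- dimnames(signal)
    list(expr = expr,
         samples = dplyr::select(samples, "sample_id", "line", "treatment",
                                 "sex", "cnv_dosage", "scan_date"),
         truth = truth)
  })
}

#' Configuration for the lifespan simulation
#'
#' Defaults emulate a postmortem brain series across the human lifespan:
#' 269 samples from fetal (negative ages, down to -0.5 years) through old
#' age (80 years), with no samples in the third trimester (the age gap
#' (-0.17, 0)); ages drawn from a fetal-plus-infancy-heavy mixture with an
#' adult tail. Gene trajectories come from four families — fetal
#' exponential decay, a jump at birth, dynamics confined to childhood
#' (0-10 years), and a late-life linear slope — with the remaining genes
#' flat; a continuous RNA-quality-like artifact loads on a gene subset.
#'
#' @param n_samples Number of samples (default 269).
#' @param frac_fetal_decay,frac_birth_jump,frac_childhood,frac_late_linear
#'   Fractions of genes in each trajectory family (defaults 0.15, 0.15,
#'   0.10, 0.10; the rest are flat).
#' @param effect_scale Typical magnitude (log2 units) of trajectory effects
#'   (default 2).
#' @param artifact_frac Fraction of genes loading on the continuous
#'   artifact (default 0.3).
#' @param artifact_sd Sd of the artifact loadings (default 0.5).
#' @param n_genes Number of genes (default 2000).
#' @param noise_sd Residual noise sd (default 0.5).
#' @return A list of class `svclean_lifespan_config`.
#' @export
lifespan_config <- function(n_samples = 269, n_genes = 2000,
                            frac_fetal_decay = 0.15, frac_birth_jump = 0.15,
                            frac_childhood = 0.10, frac_late_linear = 0.10,
                            effect_scale = 2,
                            artifact_frac = 0.3, artifact_sd = 0.5,
                            noise_sd = 0.5) {
  cfg <- as.list(environment())
  fr <- c(frac_fetal_decay, frac_birth_jump, frac_childhood, frac_late_linear)
  if (any(fr < 0) || sum(fr) > 1) abort("Trajectory fractions must be in [0,1] and sum to <= 1.")
  structure(cfg, class = "svclean_lifespan_config")
}

# Noise-free trajectory value for one gene family at given ages.
trajectory_value <- function(family, a1, a2, ages) {
  switch(family,
    flat = rep(0, length(ages)),
    fetal_decay = a1 * exp(-(ages + 0.5) / a2) * (ages < 0),
    birth_jump = a1 * (ages > 0),
    childhood = a1 * (ages * (10 - ages) / 25) * (ages > 0 & ages < 10),
    late_linear = a1 * pmax(ages - 20, 0) / 60,
    abort(sprintf("Unknown trajectory family '%s'.", family)))
}

#' Simulate a lifespan brain-expression dataset
#'
#' @param config From [lifespan_config()].
#' @param seed Required seed.
#' @return A list `(expr, samples, truth)`; `samples` has `sample_id` and
#'   `age` (years, fetal negative, none in the third-trimester gap).
#' @export
simulate_lifespan <- function(config = lifespan_config(), seed = 1) {
  cfg <- config
  with_seed(seed, {
    n <- cfg$n_samples
    n_fetal <- max(20L, round(0.15 * n))
    n_infant <- round(0.15 * n)
    n_child <- round(0.15 * n)
    n_adult <- n - n_fetal - n_infant - n_child
    if (n_adult < 20L) abort("Config leaves fewer than 20 adult samples.")
    ages <- c(runif(n_fetal, -0.5, -0.17),
              runif(n_infant, 0.01, 1),
              runif(n_child, 1, 15),
              runif(n_adult, 15, 80))
    ages <- sample(ages)                     # shuffle sample order
    samples <- tibble::tibble(sample_id = sprintf("s%03d", seq_len(n)), age = ages)

    G <- cfg$n_genes
    gene_ids <- sprintf("g%05d", seq_len(G))
    fams <- c("fetal_decay", "birth_jump", "childhood", "late_linear")
    counts <- round(G * c(cfg$frac_fetal_decay, cfg$frac_birth_jump,
                          cfg$frac_childhood, cfg$frac_late_linear))
    family <- rep("flat", G)
    family[seq_len(sum(counts))] <- rep(fams, counts)
    a1 <- ifelse(family == "flat", 0,
                 sample(c(-1, 1), G, TRUE) * (cfg$effect_scale * runif(G, 0.5, 1.5)))
    a2 <- ifelse(family == "fetal_decay", runif(G, 0.1, 0.25), NA_real_)
    artifact <- rnorm(n)
    artifact_loading <- numeric(G)
    idx_art <- sample.int(G, ceiling(cfg$artifact_frac * G))
    artifact_loading[idx_art] <- rnorm(length(idx_art), sd = cfg$artifact_sd)
    baseline <- rnorm(G, mean = 8, sd = 1.5)

    gene_truth <- tibble::tibble(gene_id = gene_ids, family = family,
                                 amplitude = a1, tau = a2,
                                 artifact_loading = artifact_loading)
    truth <- structure(list(gene_truth = gene_truth,
                            baseline = setNames(baseline, gene_ids),
                            artifact = artifact,
                            noise_sd = cfg$noise_sd,
                            kind = "lifespan",
                            seed = seed),
                       class = "svclean_truth")
    signal <- reconstruct_signal(truth, samples)
    expr <- signal + matrix(rnorm(G * n, sd = cfg$noise_sd), G, n)
    dimnames(expr) <- dimnames(signal)
    list(expr = expr, samples = samples, truth = truth)
  })
}

#' Reconstruct the noise-free signal matrix from a truth object
#'
#' The generated matrix minus this reconstruction is exactly the Gaussian
#' noise that was added — the contract that makes every recovery experiment
#' checkable.
#'
#' @param truth An `svclean_truth` object.
#' @param samples The matching sample table.
#' @return The noise-free genes x samples matrix.
#' @export
reconstruct_signal <- function(truth, samples) {
  gt <- truth$gene_truth
  G <- nrow(gt)
  n <- nrow(samples)
  if (truth$kind == "stemcell") {
    signal <- matrix(truth$baseline, G, n)
    mes <- samples$treatment == "mesendoderm"
    nec <- samples$treatment == "neurectoderm"
    signal[, mes] <- signal[, mes] + gt$delta_mes
    signal[, nec] <- signal[, nec] + gt$delta_nec
    # non-inducer lines keep marker genes flat in neurectoderm
    bad_line <- names(truth$noninducer)[truth$noninducer]
    undo <- nec & samples$line %in% bad_line
    if (any(undo) && any(gt$is_marker)) {
      signal[gt$is_marker, undo] <- signal[gt$is_marker, undo] -
        gt$delta_nec[gt$is_marker]
    }
    male <- samples$sex == "male"
    signal[, male] <- signal[, male] + gt$sex_effect
    signal <- signal + gt$cnv_effect %o% as.numeric(samples$cnv_dosage)
    signal <- signal + gt$batch_loading %o% truth$batch_levels[truth$sample_batch]
    signal <- signal + truth$line_effects[, samples$line]
  } else {
    ages <- samples$age
    signal <- matrix(truth$baseline, G, n)
    for (fam in setdiff(unique(gt$family), "flat")) {
      idx <- which(gt$family == fam)
      for (i in idx) {
        signal[i, ] <- signal[i, ] + trajectory_value(fam, gt$amplitude[i],
                                                      gt$tau[i], ages)
      }
    }
    signal <- signal + gt$artifact_loading %o% truth$artifact
  }
  dimnames(signal) <- list(gt$gene_id, samples$sample_id)
  signal
}

#' @export
print.svclean_truth <- function(x, ...) {
  cat(sprintf("<simulation truth> %s design, %d genes, noise sd %.3g, seed %s\n",
              x$kind, nrow(x$gene_truth), x$noise_sd,
              format(x$seed)))
  invisible(x)
}
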