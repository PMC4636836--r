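# The central "cleaning" operator: regress estimated surrogate variables out
# of the expression data for visualization while the protected effects (and
# always the intercept / mean expression) remain, plus the readouts used to
# study what cleaning removes under a misspecified protected model.

#' Regress surrogate variables out of expression data
#'
#' Fits the joint model `[X, S]` (protected design plus SVs) per gene by
#' least squares and subtracts only the SV component:
#' `E_clean = E - B_S S'` with `B = E W (W'W)^-1` partitioned as
#' `[B_X, B_S]`. Because the fit is joint, refitting the protected model on
#' the cleaned data returns exactly the joint-fit protected coefficients —
#' correlation between SVs and protected covariates does not bleed protected
#' signal into the subtraction (sequential residualization would).
#'
#' Cleaned data are for visualization and exploratory diagnostics only;
#' running inference on them biases significance anti-conservatively, so
#' [fit_linear_models()] refuses `svclean_cleaned` input. Fit the protected
#' design with the SVs as covariates instead.
#'
#' @param expr Numeric genes x samples matrix.
#' @param design Protected design matrix (intercept first).
#' @param svs An `svclean_svs` object, or a plain n x k matrix of factors
#'   (k = 0 leaves the data untouched).
#' @return An object of class `svclean_cleaned`: list with `values` (the
#'   cleaned matrix), `protected_design`, `sv_set`, and `provenance`
#'   (model text, k, seed, package version).
#' @export
regress_out_svs <- function(expr, design, svs) {
  expr <- check_expr(expr)
  design <- check_design(design, expr)
  if (!inherits(svs, "svclean_svs")) svs <- sv_set(as.matrix(svs))
  S <- svs$sv
  if (nrow(S) > 0L && ncol(S) > 0L && nrow(S) != ncol(expr)) {
    abort("SV matrix rows must match the number of samples.")
  }
  k <- ncol(S)
  if (k == 0L) {
    values <- expr
  } else {
    W <- cbind(unclass(design), S)
    assert_full_rank(W, arg = "[design, SVs]")
    beta <- t(qr.coef(qr(W), t(expr)))      # G x (p + k)
    beta_s <- beta[, seq.int(ncol(design) + 1L, ncol(W)), drop = FALSE]
    values <- expr - beta_s %*% t(S)
    dimnames(values) <- dimnames(expr)
  }
  structure(list(values = values,
                 protected_design = design,
                 sv_set = svs,
                 provenance = list(model_text = attr(design, "model_text") %||% "<matrix>",
                                   n_sv = k,
                                   seed = svs$seed,
                                   package_version = as.character(utils::packageVersion("svclean")))),
            class = "svclean_cleaned")
}

#' @export
print.svclean_cleaned <- function(x, ...) {
  cat(sprintf("<cleaned expression> %d genes x %d samples; model %s; k = %d SVs removed\n",
              nrow(x$values), ncol(x$values),
              x$provenance$model_text, x$provenance$n_sv))
  invisible(x)
}

#' @export
as.matrix.svclean_cleaned <- function(x, ...) x$values

#' Per-gene adjustment magnitude
#'
#' Root-mean-square difference between the raw and cleaned values across
#' samples, per gene — the size of the correction the cleaning applied. Used
#' to compare how aggressively different protected models adjust the data
#' (a more flexible lifespan model typically adjusts less).
#'
#' @param raw Numeric genes x samples matrix.
#' @param cleaned Cleaned result (or matrix) with matching dimensions.
#' @return A tibble with columns `gene_id`, `rms_adjustment`.
#' @export
adjustment_magnitude <- function(raw, cleaned) {
  raw <- check_expr(raw)
  cl <- expr_values(cleaned)
  if (!identical(dim(raw), dim(cl))) {
    abort("`raw` and `cleaned` must have identical dimensions.")
  }
  d <- raw - cl
  tibble::tibble(gene_id = rownames(raw),
                 rms_adjustment = unname(sqrt(rowMeans(d^2))))
}

#' Misspecification experiment: does cleaning preserve an injected effect?
#'
#' Runs the full pipeline (SV count by permutation, iteratively re-weighted
#' SV estimation, joint-fit cleaning) on truth-bearing synthetic data under a
#' declared protected model, then measures how much of a known injected
#' effect survives in the cleaned data. The readout is the preservation
#' ratio: the effect re-estimated from the cleaned data divided by the true
#' injected effect, averaged over effect-bearing genes whose true effect
#' exceeds `min_effect_factor` times the noise sd (small-effect genes make
#' the ratio unstable).
#'
#' A ratio near 1 means the effect was protected; near 0 means the cleaning
#' absorbed it into the surrogate variables — the fate of any real effect
#' omitted from the protected model.
#'
#' @param expr Expression matrix from [simulate_stemcell()].
#' @param samples Matching sample table.
#' @param truth Matching `svclean_truth` object.
#' @param protected_model Model string for the protected design, e.g.
#'   `"~ treatment"` or `"~ treatment + sex"`.
#' @param evaluated_effect `"sex"`, `"cnv"` or `"treatment"`: which injected
#'   effect to measure.
#' @param n_sv `"auto"` (permutation choice) or an integer.
#' @param min_effect_factor Genes enter the average only if their true
#'   effect exceeds this multiple of the noise sd (default 4).
#' @param seed Seed for the SV-count permutations.
#' @return A one-row tibble: `evaluated_effect`, `protected_model`, `n_sv`,
#'   `n_genes` (genes averaged over), `preservation_ratio`.
#' @export
misspecification_experiment <- function(expr, samples, truth, protected_model,
                                        evaluated_effect = c("sex", "cnv", "treatment"),
                                        n_sv = "auto", min_effect_factor = 4,
                                        seed = 1) {
  evaluated_effect <- match.arg(evaluated_effect)
  expr <- check_expr(expr)
  gt <- truth$gene_truth
  design <- build_design(samples, protected_model)
  k <- if (identical(n_sv, "auto")) {
    num_sv(expr, design, seed = seed)
  } else {
    as.integer(n_sv)
  }
  cleaned <- if (k > 0L) {
    svs <- estimate_svs(expr, design, n_sv = k, seed = seed)
    regress_out_svs(expr, design, svs)$values
  } else {
    expr
  }
  thr <- min_effect_factor * truth$noise_sd
  est_vs_truth <- switch(evaluated_effect,
    sex = {
      genes <- gt$gene_id[gt$sex_effect != 0 & abs(gt$sex_effect) >= thr]
      if (!length(genes)) abort("No sex-affected genes exceed the effect threshold.")
      male <- samples$sex == "male"
      est <- rowMeans(cleaned[genes, male, drop = FALSE]) -
             rowMeans(cleaned[genes, !male, drop = FALSE])
      list(est = est, truth = gt$sex_effect[match(genes, gt$gene_id)], genes = genes)
    },
    cnv = {
      # per-copy effect spans 0-2 copies: the full effect is twice the slope
      genes <- gt$gene_id[gt$cnv_effect != 0 & 2 * abs(gt$cnv_effect) >= thr]
      if (!length(genes)) abort("No CNV-affected genes exceed the effect threshold.")
      dose <- samples$cnv_dosage
      dc <- dose - mean(dose)
      est <- as.numeric(cleaned[genes, , drop = FALSE] %*% dc) / sum(dc^2)
      list(est = est, truth = gt$cnv_effect[match(genes, gt$gene_id)], genes = genes)
    },
    treatment = {
      contrast <- gt$delta_mes - gt$delta_nec
      genes <- gt$gene_id[abs(contrast) >= thr]
      if (!length(genes)) abort("No treatment-affected genes exceed the effect threshold.")
      mes <- samples$treatment == "mesendoderm"
      nec <- samples$treatment == "neurectoderm"
      est <- rowMeans(cleaned[genes, mes, drop = FALSE]) -
             rowMeans(cleaned[genes, nec, drop = FALSE])
      list(est = est, truth = contrast[match(genes, gt$gene_id)], genes = genes)
    })
  ratio <- mean(est_vs_truth$est / est_vs_truth$truth)
  tibble::tibble(evaluated_effect = evaluated_effect,
                 protected_model = protected_model,
                 n_sv = k,
                 n_genes = length(est_vs_truth$genes),
                 preservation_ratio = ratio)
}
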