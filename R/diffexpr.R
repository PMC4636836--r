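# Differential expression: per-gene least squares on the protected design
# plus surrogate variables, empirical-Bayes moderation of the residual
# variances, moderated t contrasts, and before/after result comparison.

#' Fit per-gene linear models
#'
#' Ordinary least squares of every gene on the full design `W = [X, S]`
#' (protected model plus surrogate variables as covariates). This — not
#' inference on cleaned data — is the supported route to significance:
#' cleaned data carry anti-conservative bias, so `svclean_cleaned` input is
#' refused.
#'
#' @param expr Numeric genes x samples matrix.
#' @param design Full-rank n x p design matrix (e.g. `cbind(X, svs$sv)`).
#' @return An object of class `svclean_fit`: per-gene `coefficients`
#'   (G x p), `sigma2` (residual variances), `df_residual`,
#'   `stdev_unscaled`, `cov_unscaled` (`(W'W)^-1`), `design`.
#' @export
fit_linear_models <- function(expr, design) {
  if (inherits(expr, "svclean_cleaned")) {
    abort(paste("Refusing to fit models on cleaned data: regressing out SVs and then",
                "testing biases p-values anti-conservatively. Fit the raw data with",
                "the SVs as covariates instead: fit_linear_models(raw, cbind(design, svs$sv))."))
  }
  expr <- check_expr(expr)
  if (inherits(design, "svclean_svs")) {
    abort("`design` must be a design matrix; to adjust for SVs use cbind(X, svs$sv).")
  }
  design <- check_design(design, expr)
  qd <- assert_full_rank(design)
  n <- ncol(expr)
  p <- ncol(design)
  df <- n - p
  if (df < 1L) abort("No residual degrees of freedom (n - p < 1).")
  beta <- t(qr.coef(qd, t(expr)))
  resid <- t(qr.resid(qd, t(expr)))
  sigma2 <- rowSums(resid^2) / df
  xtx_inv <- chol2inv(chol(crossprod(unclass(design))))
  dimnames(xtx_inv) <- list(colnames(design), colnames(design))
  colnames(beta) <- colnames(design)
  structure(list(coefficients = beta,
                 sigma2 = sigma2,
                 df_residual = df,
                 stdev_unscaled = sqrt(diag(xtx_inv)),
                 cov_unscaled = xtx_inv,
                 design = unclass(design),
                 gene_ids = rownames(expr)),
            class = "svclean_fit")
}

# Inverse of the trigamma function by monotone bisection/uniroot on log scale.
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(Inf)
    # trigamma is decreasing from Inf (x -> 0) to 0 (x -> Inf)
    lo <- 1e-8; hi <- 1e8
    if (trigamma(lo) < yy) return(lo)
    if (trigamma(hi) > yy) return(hi)
    stats::uniroot(function(x) trigamma(exp(x)) - yy,
                   lower = log(lo), upper = log(hi), tol = 1e-12)$root |> exp()
  }, numeric(1))
}

#' Empirical-Bayes moderation of residual variances
#'
#' Shrinks every gene's residual variance toward a common prior estimated by
#' matching the first two moments of `log(s^2)` to the scaled-F model (via
#' the digamma/trigamma identities; the trigamma inverse is found by
#' monotone root-finding). The moderated variance is the degrees-of-freedom-
#' weighted combination `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)` and the
#' moderated t uses `d0 + d` degrees of freedom. When the `log(s^2)` spread
#' is no larger than pure sampling noise, the prior df is infinite and every
#' `s~^2` collapses to `s0^2`; `prior_df = 0` can be forced to recover
#' ordinary t-statistics.
#'
#' @param fit Result of [fit_linear_models()]; needs at least 10 genes for a
#'   stable hyperparameter estimate.
#' @param prior_df Optional override of the estimated prior degrees of
#'   freedom `d0` (use `0` for ordinary t, `Inf` for full pooling).
#' @return An object of class `svclean_modfit` extending the fit with
#'   `df_prior`, `s2_prior`, `s2_post`, per-coefficient moderated `t` and
#'   `p_value` matrices, and a moderated overall `F` for the non-intercept
#'   columns.
#' @export
moderate <- function(fit, prior_df = NULL) {
  if (!inherits(fit, "svclean_fit")) abort("`fit` must come from fit_linear_models().")
  G <- length(fit$sigma2)
  if (G < 10L) abort("Need at least 10 genes for stable hyperparameter estimation.")
  s2 <- fit$sigma2
  zero <- s2 <= 0
  if (any(zero)) {
    minpos <- min(s2[!zero])
    inform(sprintf("%d gene(s) with zero residual variance set to the minimum positive variance before moderation.",
                   sum(zero)))
    s2[zero] <- minpos
  }
  d <- fit$df_residual
  if (is.null(prior_df)) {
    e <- log(s2) - digamma(d / 2) + log(d / 2)
    ve <- stats::var(e)
    excess <- ve - trigamma(d / 2)
    if (is.finite(excess) && excess > 0) {
      d0 <- 2 * trigamma_inverse(excess)
      s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_2 <- exp(mean(e))
    }
  } else {
    d0 <- prior_df
    e <- log(s2) - digamma(d / 2) + log(d / 2)
    s0_2 <- if (d0 == 0) NA_real_
            else if (is.infinite(d0)) exp(mean(e))
            else exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_post <- if (is.infinite(d0)) rep(s0_2, G)
             else if (d0 == 0) s2
             else (d0 * s0_2 + d * s2) / (d0 + d)
  se <- sqrt(s2_post) %o% fit$stdev_unscaled
  tstat <- fit$coefficients / se
  df_total <- d0 + d
  p <- 2 * stats::pt(abs(tstat), df = df_total, lower.tail = FALSE)
  dimnames(tstat) <- dimnames(fit$coefficients)
  dimnames(p) <- dimnames(fit$coefficients)
  # moderated overall F across non-intercept columns
  pcols <- setdiff(colnames(fit$design), "(Intercept)")
  Fstat <- NULL; Fp <- NULL
  if (length(pcols) >= 1L) {
    Bsub <- fit$coefficients[, pcols, drop = FALSE]
    Vsub <- fit$cov_unscaled[pcols, pcols, drop = FALSE]
    quad <- rowSums((Bsub %*% chol2inv(chol(Vsub))) * Bsub)
    Fstat <- quad / (length(pcols) * s2_post)
    Fp <- stats::pf(Fstat, length(pcols), df_total, lower.tail = FALSE)
  }
  out <- fit
  out$sigma2 <- s2
  out$df_prior <- d0
  out$s2_prior <- s0_2
  out$s2_post <- s2_post
  out$t <- tstat
  out$p_value <- p
  out$F <- Fstat
  out$F_p_value <- Fp
  class(out) <- c("svclean_modfit", "svclean_fit")
  out
}

#' Test a contrast of design coefficients
#'
#' Computes the moderated t-test of `c' beta` per gene for a numeric
#' contrast over the design columns — e.g. the mesendoderm-minus-neurectoderm
#' comparison in a 3-level treatment coding where both are non-reference
#' levels. Benjamini-Hochberg q-values are attached.
#'
#' @param fit Result of [moderate()].
#' @param contrast Numeric vector over the design columns, or a named vector
#'   naming a subset of them (others 0).
#' @return A tibble: `gene_id`, `estimate` (log2 fold change), `t`,
#'   `p_value`, `q_value`, sorted as the input genes.
#' @export
de_contrast <- function(fit, contrast) {
  if (!inherits(fit, "svclean_modfit")) abort("`fit` must come from moderate().")
  p <- ncol(fit$coefficients)
  cvec <- numeric(p)
  if (!is.null(names(contrast))) {
    miss <- setdiff(names(contrast), colnames(fit$coefficients))
    if (length(miss)) abort(sprintf("Unknown design column(s) in contrast: %s",
                                    paste(miss, collapse = ", ")))
    cvec[match(names(contrast), colnames(fit$coefficients))] <- contrast
  } else {
    if (length(contrast) != p) {
      abort(sprintf("Contrast length %d does not match the %d design columns.",
                    length(contrast), p))
    }
    cvec <- as.numeric(contrast)
  }
  if (all(cvec == 0)) abort("Contrast is all zeros.")
  est <- as.numeric(fit$coefficients %*% cvec)
  v <- as.numeric(t(cvec) %*% fit$cov_unscaled %*% cvec)
  if (v <= 0) abort("Contrast is inestimable under this design.")
  tstat <- est / sqrt(v * fit$s2_post)
  pval <- 2 * stats::pt(abs(tstat), df = fit$df_prior + fit$df_residual,
                        lower.tail = FALSE)
  tibble::tibble(gene_id = fit$gene_ids,
                 estimate = est,
                 t = tstat,
                 p_value = pval,
                 q_value = stats::p.adjust(pval, method = "BH"))
}

#' Compare two differential-expression results
#'
#' For matched gene sets, reports the fraction of genes with strictly
#' smaller p-values in `result_a` than in `result_b`, and the Spearman rank
#' correlation of the `-log10 p` orderings (how well the relative gene
#' ranking is preserved between the two analyses).
#'
#' @param result_a,result_b Tibbles from [de_contrast()] (columns `gene_id`,
#'   `p_value`) over identical gene sets.
#' @return A one-row tibble: `fraction_smaller_a`, `rank_correlation`, `n_genes`.
#' @export
compare_de_results <- function(result_a, result_b) {
  if (!setequal(result_a$gene_id, result_b$gene_id) ||
      nrow(result_a) != nrow(result_b)) {
    abort("The two results must cover identical gene sets.")
  }
  b <- result_b[match(result_a$gene_id, result_b$gene_id), ]
  tibble::tibble(
    fraction_smaller_a = mean(result_a$p_value < b$p_value),
    rank_correlation = stats::cor(-log10(result_a$p_value), -log10(b$p_value),
                                  method = "spearman"),
    n_genes = nrow(result_a))
}

#' @export
print.svclean_fit <- function(x, ...) {
  cat(sprintf("<per-gene linear fit> %d genes, %d design columns, %d residual df\n",
              nrow(x$coefficients), ncol(x$coefficients), x$df_residual))
  if (inherits(x, "svclean_modfit")) {
    cat(sprintf("  moderated: prior df %.3g, prior variance %.4g\n",
                x$df_prior, x$s2_prior))
  }
  invisible(x)
}

#' @rdname moderate
#' @param x An `svclean_modfit` object.
#' @param ... Unused.
#' @method tidy svclean_modfit
#' @export
tidy.svclean_modfit <- function(x, ...) {
  tibble::as_tibble(x$coefficients, rownames = "gene_id") %>%
    tidyr::pivot_longer(-"gene_id", names_to = "term", values_to = "estimate") %>%
    dplyr::left_join(
      tibble::as_tibble(x$t, rownames = "gene_id") %>%
        tidyr::pivot_longer(-"gene_id", names_to = "term", values_to = "statistic"),
      by = c("gene_id", "term")) %>%
    dplyr::left_join(
      tibble::as_tibble(x$p_value, rownames = "gene_id") %>%
        tidyr::pivot_longer(-"gene_id", names_to = "term", values_to = "p_value"),
      by = c("gene_id", "term"))
}

#' @rdname moderate
#' @method glance svclean_modfit
#' @export
glance.svclean_modfit <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$coefficients),
                 n_terms = ncol(x$coefficients),
                 df_residual = x$df_residual,
                 df_prior = x$df_prior,
                 s2_prior = x$s2_prior)
}
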