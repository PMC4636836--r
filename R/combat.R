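# Known-batch empirical-Bayes adjustment (the location/scale model with
# parametric priors), used as the comparison method for surrogate-variable
# cleaning. Requires categorical batch labels; a continuous artifact (such
# as RNA quality) cannot be expressed as batches, which is exactly where the
# surrogate-variable route retains an advantage.

#' Empirical-Bayes known-batch adjustment
#'
#' Removes additive and multiplicative batch effects gene by gene with
#' empirical-Bayes shrinkage across genes:
#'
#' 1. Fit the pooled model (batch indicators plus optional covariates) per
#'    gene; standardize the data with the sample-size-weighted grand mean,
#'    the covariate fit, and the pooled residual variance.
#' 2. Estimate per-batch, per-gene location (`gamma_hat`) and scale
#'    (`delta_hat^2`) on the standardized data.
#' 3. Shrink both toward cross-gene priors (normal location, inverse-gamma
#'    scale, hyperparameters by method of moments within batch), iterating
#'    the coupled `gamma*`/`delta^2*` updates until the relative change is
#'    below `tol`.
#' 4. Back-transform with batch effects removed and the grand mean and
#'    covariate effects restored.
#'
#' Covariates protect known biology from removal; they must not be
#' confounded with batch (the combined design must be full rank), and every
#' batch needs at least two samples. With a single batch the data are
#' returned unchanged.
#'
#' @param expr Numeric genes x samples matrix (log2 scale).
#' @param batch Factor/character vector of batch labels, one per sample.
#' @param covariates Optional protected design matrix from [build_design()]
#'   (its intercept is absorbed into the batch means); `NULL` means
#'   intercept-only.
#' @param parametric Must be `TRUE`; only the parametric priors are
#'   implemented.
#' @param tol Relative-change convergence tolerance for the coupled EB
#'   updates (default 1e-4).
#' @param return_params If `TRUE`, also return the per-batch estimates and
#'   shrunken parameters.
#' @return The adjusted matrix, or (with `return_params = TRUE`) a list
#'   `list(corrected, params)` where `params` holds `gamma_hat`,
#'   `gamma_star`, `gamma_bar`, `delta_hat2`, `delta_star2` per batch.
#' @export
combat_adjust <- function(expr, batch, covariates = NULL, parametric = TRUE,
                          tol = 1e-4, return_params = FALSE) {
  if (!isTRUE(parametric)) abort("Only the parametric EB priors are implemented.")
  expr <- check_expr(expr)
  batch <- factor(batch)
  n <- ncol(expr)
  if (length(batch) != n) abort("`batch` must have one label per sample.")
  counts <- table(batch)
  if (any(counts < 2L)) {
    abort(sprintf("Every batch needs >= 2 samples; offending batch(es): %s",
                  paste(names(counts)[counts < 2L], collapse = ", ")))
  }
  if (nlevels(batch) == 1L) {
    inform("Single batch: nothing to adjust; returning the input unchanged.")
    if (return_params) return(list(corrected = expr, params = NULL))
    return(expr)
  }
  B <- stats::model.matrix(~ 0 + batch)           # n x n_batch indicators
  colnames(B) <- levels(batch)
  C <- NULL
  if (!is.null(covariates)) {
    C <- unclass(check_design(covariates, expr, arg = "covariates"))
    # drop intercept-like columns; batch means absorb the grand mean
    const <- apply(C, 2L, function(x) stats::sd(x) == 0)
    C <- C[, !const, drop = FALSE]
    if (ncol(C) == 0L) C <- NULL
  }
  X <- cbind(B, C)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    abort(sprintf("Batch is confounded with covariate(s); the combined design is rank deficient at: %s. Known-batch adjustment cannot separate these effects.",
                  paste(bad, collapse = ", ")))
  }
  nb <- nlevels(batch)
  beta <- qr.coef(qx, t(expr))                    # (nb + q) x G
  grand_mean <- as.numeric(crossprod(counts / n, beta[seq_len(nb), , drop = FALSE]))
  fitted_all <- t(X %*% beta)
  var_pooled <- rowMeans((expr - fitted_all)^2)
  if (any(var_pooled <= 0)) {
    abort("Some genes have zero pooled variance; cannot standardize.")
  }
  stand_mean <- matrix(grand_mean, nrow(expr), n)
  if (!is.null(C)) {
    stand_mean <- stand_mean + t(C %*% beta[-seq_len(nb), , drop = FALSE])
  }
  s_data <- (expr - stand_mean) / sqrt(var_pooled)

  gamma_hat <- vapply(levels(batch), function(b)
    rowMeans(s_data[, batch == b, drop = FALSE]), numeric(nrow(expr)))
  delta_hat2 <- vapply(levels(batch), function(b)
    apply(s_data[, batch == b, drop = FALSE], 1L, stats::var), numeric(nrow(expr)))

  gamma_bar <- colMeans(gamma_hat)
  tau2_bar <- apply(gamma_hat, 2L, stats::var)
  # inverse-gamma hyperparameters by method of moments on delta_hat^2
  m_d <- colMeans(delta_hat2)
  v_d <- apply(delta_hat2, 2L, stats::var)
  a_prior <- (2 * v_d + m_d^2) / v_d
  b_prior <- (m_d * v_d + m_d^3) / v_d

  gamma_star <- gamma_hat
  delta_star2 <- delta_hat2
  for (j in seq_len(nb)) {
    b <- levels(batch)[j]
    nj <- sum(batch == b)
    sd_b <- s_data[, batch == b, drop = FALSE]
    g_old <- gamma_hat[, j]
    d_old <- delta_hat2[, j]
    repeat {
      g_new <- (tau2_bar[j] * nj * gamma_hat[, j] + d_old * gamma_bar[j]) /
               (tau2_bar[j] * nj + d_old)
      sum2 <- rowSums((sd_b - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[j]) / (nj / 2 + a_prior[j] - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
      g_old <- g_new
      d_old <- d_new
      if (change < tol) break
    }
    gamma_star[, j] <- g_old
    delta_star2[, j] <- d_old
  }

  adjusted <- s_data
  for (j in seq_len(nb)) {
    idx <- batch == levels(batch)[j]
    adjusted[, idx] <- (s_data[, idx, drop = FALSE] - gamma_star[, j]) /
                       sqrt(delta_star2[, j])
  }
  # EB shrinkage leaves a small per-gene residual location; re-center so the
  # pooled grand mean is restored exactly
  adjusted <- adjusted - rowMeans(adjusted)
  corrected <- adjusted * sqrt(var_pooled) + stand_mean
  dimnames(corrected) <- dimnames(expr)
  if (return_params) {
    return(list(corrected = corrected,
                params = list(gamma_hat = gamma_hat, gamma_star = gamma_star,
                              gamma_bar = gamma_bar, tau2_bar = tau2_bar,
                              delta_hat2 = delta_hat2, delta_star2 = delta_star2,
                              a_prior = a_prior, b_prior = b_prior,
                              grand_mean = grand_mean, var_pooled = var_pooled)))
  }
  corrected
}
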