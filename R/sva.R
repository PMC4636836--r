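# Surrogate variable estimation under a protected design: permutation-based
# choice of the number of SVs, and iteratively re-weighted extraction of the
# SVs themselves.

#' Residualize expression on a design
#'
#' Projects every gene (row) of `expr` onto the orthogonal complement of the
#' design's column space: `E (I - X (X'X)^-1 X')`. Used to confine surrogate
#' variable estimation to variation the protected model does not explain.
#'
#' @param expr Numeric genes x samples matrix.
#' @param design Full-rank n x p design matrix, rows aligned with samples.
#' @return The residual matrix, same dimnames as `expr`.
#' @export
residualize <- function(expr, design) {
  expr <- check_expr(expr)
  design <- check_design(design, expr)
  qd <- assert_full_rank(design)
  res <- t(qr.resid(qd, t(expr)))
  dimnames(res) <- dimnames(expr)
  res
}

#' Estimate the number of surrogate variables by permutation
#'
#' Compares the eigenvalue spectrum of the protected-model residuals against
#' a permutation null in which each gene's values are independently shuffled
#' across samples (destroying all sample-level structure while preserving
#' each gene's marginal distribution) and re-residualized on the same design.
#' Component `i` gets the p-value `p_i` = fraction of permutations whose
#' `i`-th eigenvalue proportion is at least the observed one; the returned
#' count is the largest `m` such that `p_1, ..., p_m` are all at or below
#' `alpha` (contiguous from the first component).
#'
#' @param expr Numeric genes x samples matrix.
#' @param design Protected design matrix.
#' @param n_permutations Number of permutations `B` (default 20).
#' @param alpha Per-component significance level (default 0.10).
#' @param seed Seed for the permutation stream (required for reproducibility).
#' @param max_perm_cells Guard on the total permutation workload
#'   `B * G * n`; raise it deliberately for very large problems.
#' @return Integer number of surrogate variables (possibly 0).
#' @export
num_sv <- function(expr, design, n_permutations = 20, alpha = 0.10, seed = 1,
                   max_perm_cells = 2e9) {
  expr <- check_expr(expr)
  design <- check_design(design, expr)
  if (n_permutations < 1) abort("`n_permutations` must be >= 1.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  n <- ncol(expr)
  p <- design_rank(design)
  if (n - p < 2L) abort("Need at least 2 residual degrees of freedom (n - rank(X) >= 2).")
  workload <- as.double(n_permutations) * nrow(expr) * n
  if (workload > max_perm_cells) {
    abort(sprintf("Permutation workload %.3g exceeds max_perm_cells = %.3g; raise the cap explicitly if intended.",
                  workload, max_perm_cells))
  }
  m <- n - p                                # informative residual components
  eig_props <- function(R) {
    ev <- eigen(crossprod(R), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    ev / sum(ev)
  }
  obs <- eig_props(residualize(expr, design))[seq_len(m)]
  with_seed(seed, {
    exceed <- integer(m)
    for (b in seq_len(n_permutations)) {
      perm <- t(apply(expr, 1L, sample))
      dimnames(perm) <- dimnames(expr)
      pb <- eig_props(residualize(perm, design))[seq_len(m)]
      exceed <- exceed + (pb >= obs)
    }
    # finite-sample permutation p-value: the observed statistic counts as
    # one member of its own null ensemble
    pvals <- (1 + exceed) / (n_permutations + 1)
    sig <- pvals <= alpha
    k <- if (!sig[1L]) 0L else (which(!c(sig, FALSE))[1L] - 1L)
    as.integer(min(k, m))
  })
}

# Storey-type pi0: proportion of null hypotheses from the p-value histogram,
# smoothed over a lambda grid and read off near lambda -> 1.
estimate_pi0 <- function(p, lambda = seq(0, 0.95, by = 0.05)) {
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  pi0 <- tryCatch({
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    stats::predict(fit, x = max(lambda))$y
  }, error = function(e) NA_real_)
  if (!is.finite(pi0) || pi0 <= 0) {
    warn("pi0 estimate did not converge; falling back to pi0 = 1.")
    pi0 <- 1
  }
  min(pi0, 1)
}

# Local false-discovery rate (posterior probability of being null) from a
# p-value vector: probit transform, kernel density estimate of the p-value
# density, lfdr = pi0 * null density / observed density, made monotone
# nondecreasing in p and truncated to [0, 1].
local_fdr <- function(p, adjust = 1.5, eps = 1e-8) {
  p <- pmin(pmax(p, eps), 1 - eps)
  pi0 <- estimate_pi0(p)
  x <- stats::qnorm(p)
  d <- stats::density(x, adjust = adjust)
  y <- stats::approx(d$x, d$y, xout = x, rule = 2)$y
  lfdr <- pi0 * stats::dnorm(x) / pmax(y, .Machine$double.eps)
  o <- order(p)
  lfdr[o] <- cummax(lfdr[o])
  pmin(lfdr, 1)
}

# Row-wise F-test p-values comparing nested designs (full vs reduced).
rowwise_f_pvalues <- function(expr, full, reduced) {
  n <- ncol(expr)
  q_full <- qr(full); q_red <- qr(reduced)
  df1 <- q_full$rank - q_red$rank
  df2 <- n - q_full$rank
  if (df1 < 1L || df2 < 1L) abort("Nested F-test has no degrees of freedom.")
  rss_full <- rowSums(t(qr.resid(q_full, t(expr)))^2)
  rss_red <- rowSums(t(qr.resid(q_red, t(expr)))^2)
  fstat <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  stats::pf(pmax(fstat, 0), df1, df2, lower.tail = FALSE)
}

#' Estimate surrogate variables (iteratively re-weighted)
#'
#' Extracts `n_sv` sample-level latent factors capturing systematic
#' heterogeneity orthogonal to the protected design. The algorithm:
#'
#' 1. Initialize `S` as the first `n_sv` right singular vectors of the
#'    residualized data.
#' 2. Per iteration, compute for every gene the p-value of association with
#'    the current `S` given the protected design `X` (F-test of `[X, S]` vs
#'    `X`) and with `X` itself (F-test of `X` vs intercept); convert both
#'    p-value sets to posterior null probabilities via a Storey-type
#'    `pi0`/local-fdr estimate; set the gene weight
#'    `w_g = P(associated with S) * (1 - P(associated with X))`.
#' 3. Recompute `S` as the first `n_sv` right singular vectors of the
#'    row-weighted data `diag(w) E`.
#'
#' Genes driven by the protected effects get weights near 0, which is what
#' protects those effects from being absorbed into the SVs. With
#' `n_iterations = 0` the result is the plain (unweighted) SVD of residuals.
#'
#' @param expr Numeric genes x samples matrix.
#' @param design Protected design matrix (full rank, intercept first).
#' @param n_sv Number of surrogate variables, `1 <= n_sv <= n - rank(X)`
#'   (use [num_sv()] for an automatic choice).
#' @param n_iterations Re-weighting iterations (default 5).
#' @param seed Recorded in the result for provenance; the algorithm itself is
#'   deterministic.
#' @return An object of class `svclean_svs`: list with `sv` (n x k
#'   orthonormal matrix, columns `SV1..SVk`), `n_sv`, `gene_weights`
#'   (in \[0, 1\]), `method`, `n_iterations`, `seed`.
#' @export
estimate_svs <- function(expr, design, n_sv, n_iterations = 5, seed = NULL) {
  expr <- check_expr(expr)
  design <- check_design(design, expr)
  assert_full_rank(design)
  n <- ncol(expr)
  p <- design_rank(design)
  if (n_sv < 1L || n_sv > n - p) {
    abort(sprintf("`n_sv` must be between 1 and n - rank(X) = %d.", n - p))
  }
  k <- as.integer(n_sv)
  resid0 <- residualize(expr, design)
  sv <- svd(resid0, nu = 0, nv = k)$v
  w <- rep(1, nrow(expr))
  iters_done <- 0L
  if (n_iterations > 0) {
    intercept <- matrix(1, n, 1)
    intercept_only <- p <= 1L
    for (it in seq_len(n_iterations)) {
      p_sv <- rowwise_f_pvalues(expr, cbind(design, sv), design)
      lfdr_sv <- local_fdr(p_sv)
      # intercept-only protection: no effects beyond the mean to shield
      lfdr_x <- if (intercept_only) rep(1, nrow(expr)) else
        local_fdr(rowwise_f_pvalues(expr, design, intercept))
      w <- pmin(pmax((1 - lfdr_sv) * lfdr_x, 0), 1)
      sv <- svd(expr * w, nu = 0, nv = k)$v
      iters_done <- it
    }
  }
  # orthonormal by construction; fix SVD sign ambiguity
  flip <- ifelse(sv[1L, ] < 0, -1, 1)
  sv <- sweep(sv, 2L, flip, `*`)
  colnames(sv) <- paste0("SV", seq_len(k))
  rownames(sv) <- colnames(expr)
  structure(list(sv = sv, n_sv = k, gene_weights = w, method = "irw",
                 n_iterations = iters_done, seed = seed),
            class = "svclean_svs")
}

#' Construct a surrogate-variable set from a known matrix
#'
#' Wraps an externally supplied (or empty) SV matrix in the container
#' returned by [estimate_svs()], orthonormalizing its columns. Useful for
#' zero-SV baselines and for supplying known factors in tests.
#'
#' @param sv Numeric n x k matrix (k may be 0).
#' @param method Label recorded in the result.
#' @return An object of class `svclean_svs`.
#' @export
sv_set <- function(sv, method = "supplied") {
  sv <- as.matrix(sv)
  storage.mode(sv) <- "double"
  if (ncol(sv) > 0L) {
    sv <- qr.Q(qr(sv))
    flip <- ifelse(sv[1L, ] < 0, -1, 1)
    sv <- sweep(sv, 2L, flip, `*`)
    colnames(sv) <- paste0("SV", seq_len(ncol(sv)))
  }
  structure(list(sv = sv, n_sv = ncol(sv), gene_weights = NULL,
                 method = method, n_iterations = 0L, seed = NULL),
            class = "svclean_svs")
}

#' @export
print.svclean_svs <- function(x, ...) {
  cat(sprintf("<surrogate variables> k = %d over %d samples (%s, %d iteration%s)\n",
              x$n_sv, nrow(x$sv), x$method, x$n_iterations,
              if (x$n_iterations == 1) "" else "s"))
  invisible(x)
}

#' @rdname estimate_svs
#' @param x An `svclean_svs` object.
#' @param ... Unused.
#' @method tidy svclean_svs
#' @export
tidy.svclean_svs <- function(x, ...) {
  tibble::as_tibble(x$sv, rownames = "sample_id") %>%
    tidyr::pivot_longer(dplyr::starts_with("SV"),
                        names_to = "sv", values_to = "value")
}

#' @rdname estimate_svs
#' @method glance svclean_svs
#' @export
glance.svclean_svs <- function(x, ...) {
  tibble::tibble(n_sv = x$n_sv, method = x$method,
                 n_iterations = x$n_iterations,
                 mean_gene_weight = if (is.null(x$gene_weights)) NA_real_
                                    else mean(x$gene_weights))
}
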