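test_that("cleaning with orthogonal SVs collapses to direct projection", {
  set.seed(1)
  n <- 12
  X <- two_group_design(n)
  S <- qr.Q(qr(residuals(lm(matrix(rnorm(n * 2), n, 2) ~ X - 1))))
  e <- rand_expr(30, n, seed = 2)
  cl <- regress_out_svs(e, X, sv_set(S))
  direct <- e - e %*% S %*% solve(crossprod(S)) %*% t(S)
  expect_lt(max(abs(cl$values - direct)), 1e-10)
})

test_that("zero SVs leave the data exactly untouched", {
  e <- rand_expr(15, 8, seed = 3)
  X <- two_group_design(8)
  cl <- regress_out_svs(e, X, sv_set(matrix(numeric(0), 8, 0)))
  expect_identical(cl$values, e)
})

test_that("joint-fit subtraction matches an explicit normal-equations oracle", {
  # 4 genes x 6 samples with deliberately correlated X and S
  set.seed(7)
  n <- 6
  X <- two_group_design(n)
  S <- matrix(X[, 2] * 0.7 + rnorm(n) * 0.5, n, 1)
  S <- S / sqrt(sum(S^2))
  e <- rand_expr(4, n, seed = 8)
  cl <- regress_out_svs(e, X, sv_set(S))
  S_o <- cl$sv_set$sv                     # sv_set re-orthonormalizes / fixes sign
  W <- cbind(X, S_o)
  for (g in 1:4) {
    beta <- solve(t(W) %*% W, t(W) %*% e[g, ])
    expect_equal(unname(cl$values[g, ]),
                 unname(e[g, ] - as.numeric(S_o) * beta[3, 1]),
                 tolerance = 1e-10)
  }
})

test_that("protected coefficients refit on cleaned data equal the joint fit", {
  set.seed(9)
  n <- 20
  X <- two_group_design(n)
  f <- 0.6 * X[, 2] + rnorm(n)            # SV correlated with the design
  e <- rand_expr(40, n, seed = 10) + matrix(rnorm(40), 40, 1) %*% t(f)
  svs <- sv_set(matrix(f, n, 1))
  cl <- regress_out_svs(e, X, svs)
  W <- cbind(X, svs$sv)
  joint <- t(qr.coef(qr(W), t(e)))[, 1:2]
  refit <- t(qr.coef(qr(unclass(X)), t(cl$values)))
  expect_lt(max(abs(refit - joint)), 1e-8)

  # partial correlation of cleaned genes with the SV, given X, is zero:
  # residualize both on X and check orthogonality
  s_res <- residuals(lm(svs$sv ~ X - 1))
  expect_lt(max(abs(residualize(cl$values, unclass(X)) %*% s_res)), 1e-8)
})

test_that("joint fitting differs from sequential residualization when X and S correlate", {
  set.seed(12)
  n <- 18
  X <- two_group_design(n)
  f <- 0.8 * X[, 2] + 0.4 * rnorm(n)
  svs <- sv_set(matrix(f, n, 1))
  beta_true <- 1.5
  e <- rand_expr(25, n, seed = 13)
  e <- e + matrix(beta_true, 25, 1) %*% t(X[, 2])
  joint <- regress_out_svs(e, X, svs)$values
  seq_clean <- e - (e %*% svs$sv) %*% t(svs$sv)   # ignores X: sequential route
  expect_gt(max(abs(joint - seq_clean)), 0.01)
  # only the joint route preserves the protected effect estimate
  b_joint <- t(qr.coef(qr(unclass(X)), t(joint)))[, 2]
  b_full <- t(qr.coef(qr(cbind(X, svs$sv)), t(e)))[, 2]
  expect_lt(max(abs(b_joint - b_full)), 1e-8)
  b_seq <- t(qr.coef(qr(unclass(X)), t(seq_clean)))[, 2]
  expect_gt(max(abs(b_seq - b_full)), 0.01)
})

test_that("adjustment magnitude is the per-gene RMS of the correction", {
  e <- rand_expr(5, 6, seed = 14)
  expect_equal(adjustment_magnitude(e, e)$rms_adjustment, rep(0, 5))
  d <- c(1, -1, 2, 0, 3, -2)
  e2 <- e; e2[2, ] <- e[2, ] - d
  am <- adjustment_magnitude(e, e2)
  expect_equal(am$rms_adjustment[2], sqrt(mean(d^2)))
  expect_equal(am$rms_adjustment[-2], rep(0, 4))
  expect_error(adjustment_magnitude(e, e[, 1:3]), "identical dimensions")
})

test_that("inference is refused on cleaned data by construction", {
  e <- rand_expr(20, 10, seed = 15)
  X <- two_group_design(10)
  cl <- regress_out_svs(e, X, sv_set(matrix(rnorm(10), 10, 1)))
  expect_error(fit_linear_models(cl, X), "anti-conservative")
  # but diagnostics accept cleaned results directly
  expect_s3_class(pca(cl), "svclean_pca")
})

test_that("misspecification experiment removes unprotected and keeps protected effects", {
  sim <- simulate_stemcell(stemcell_config(n_genes = 1200), seed = 42)
  unprot <- misspecification_experiment(sim$expr, sim$samples, sim$truth,
                                        "~ treatment", "sex", seed = 42)
  expect_lt(unprot$preservation_ratio, 0.10)
  prot <- misspecification_experiment(sim$expr, sim$samples, sim$truth,
                                      "~ treatment + sex", "sex", seed = 42)
  expect_gt(prot$preservation_ratio, 0.9)
  expect_lt(prot$preservation_ratio, 1.1)
  expect_error(
    misspecification_experiment(sim$expr, sim$samples, sim$truth,
                                "~ treatment", "sex", min_effect_factor = 1e6),
    "threshold")
})
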