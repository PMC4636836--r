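test_that("per-gene least squares matches an independent normal-equations solve", {
  e <- rand_expr(5, 10, seed = 1)
  W <- cbind(intercept_design(10), x = rnorm(10), z = rnorm(10))
  fit <- fit_linear_models(e, W)
  for (g in 1:5) {
    beta <- solve(t(W) %*% W, t(W) %*% e[g, ])
    expect_equal(unname(fit$coefficients[g, ]), unname(beta[, 1]),
                 tolerance = 1e-10)
  }
  # noise-free gene equal to a design column
  e2 <- mk_expr(rbind(W[, 2], W[, 2]))
  fit2 <- fit_linear_models(e2, W)
  expect_equal(unname(fit2$coefficients[1, ]), c(0, 1, 0), tolerance = 1e-10)
  expect_equal(fit2$sigma2[[1]], 0)
  # permutation of samples together with design rows changes nothing
  p <- sample(10)
  fit3 <- fit_linear_models(e[, p], W[p, ])
  expect_equal(fit3$coefficients, fit$coefficients, tolerance = 1e-10)
})

test_that("moderation obeys the shrinkage identity and its limit cases", {
  set.seed(2)
  e <- mk_expr(matrix(rnorm(300 * 12, 0, rep(sqrt(rchisq(300, 4) / 4), 12)),
                      300, 12))
  W <- two_group_design(12)
  fit <- fit_linear_models(e, W)
  mod <- moderate(fit)
  d0 <- mod$df_prior; dg <- mod$df_residual
  expect_equal(mod$s2_post,
               (d0 * mod$s2_prior + dg * mod$sigma2) / (d0 + dg),
               tolerance = 1e-10)
  expect_true(all(mod$s2_post >= pmin(mod$sigma2, mod$s2_prior) - 1e-12))
  expect_true(all(mod$s2_post <= pmax(mod$sigma2, mod$s2_prior) + 1e-12))

  # d0 = 0: ordinary t
  m0 <- moderate(fit, prior_df = 0)
  t_ord <- fit$coefficients[, 2] / sqrt(fit$sigma2 * fit$stdev_unscaled[2]^2)
  expect_equal(unname(m0$t[, 2]), unname(t_ord), tolerance = 1e-10)

  # d0 = Inf: fully pooled variance
  mI <- moderate(fit, prior_df = Inf)
  expect_equal(unname(mI$s2_post), rep(mI$s2_prior, 300))
  expect_equal(unname(mI$t[, 2]),
               unname(fit$coefficients[, 2] /
                        (sqrt(mI$s2_prior) * fit$stdev_unscaled[2])),
               tolerance = 1e-10)

  expect_error(moderate(fit_linear_models(e[1:5, ], W)), "at least 10 genes")
})

test_that("homoscedastic genes collapse to the infinite-prior limit", {
  set.seed(3)
  sd0 <- 0.7
  e <- mk_expr(matrix(rnorm(2000 * 50, 0, sd0), 2000, 50))
  mod <- moderate(fit_linear_models(e, two_group_design(50)))
  # log s^2 spread is at (or below) pure sampling noise -> huge/infinite d0
  expect_gt(mod$df_prior, 48)
  expect_equal(mod$s2_prior, sd0^2, tolerance = 0.1)
})

test_that("moderated statistics agree with the reference EB implementation", {
  set.seed(4)
  e <- mk_expr(matrix(rnorm(400 * 14, 0, rep(sqrt(rchisq(400, 6) / 6), 14)),
                      400, 14))
  W <- two_group_design(14)
  mod <- moderate(fit_linear_models(e, W))
  ref <- limma::eBayes(limma::lmFit(e, W))
  expect_equal(mod$df_prior, ref$df.prior, tolerance = 1e-6)
  expect_equal(mod$s2_prior, ref$s2.prior, tolerance = 1e-6)
  expect_equal(unname(mod$t[, 2]), unname(ref$t[, 2]), tolerance = 1e-8)
  expect_equal(unname(mod$p_value[, 2]), unname(ref$p.value[, 2]),
               tolerance = 1e-8)
})

test_that("null moderated p-values are uniform", {
  ks <- sapply(1:10, function(s) {
    set.seed(s)
    e <- mk_expr(matrix(rnorm(2000 * 12), 2000, 12))
    de <- de_contrast(moderate(fit_linear_models(e, two_group_design(12))),
                      c(x = 1))
    suppressWarnings(ks.test(de$p_value, "punif")$statistic)
  })
  expect_gte(sum(ks < 0.05), 9)
})

test_that("contrasts reduce to single-coefficient tests and validate input", {
  set.seed(5)
  e <- rand_expr(50, 12, seed = 5)
  W <- two_group_design(12)
  mod <- moderate(fit_linear_models(e, W))
  de_named <- de_contrast(mod, c(x = 1))
  de_vec <- de_contrast(mod, c(0, 1))
  expect_equal(de_named$t, unname(mod$t[, 2]))
  expect_equal(de_named$p_value, de_vec$p_value)
  expect_equal(de_named$q_value, p.adjust(de_named$p_value, "BH"))
  # q-values monotone in p
  o <- order(de_named$p_value)
  expect_true(all(diff(de_named$q_value[o]) >= -1e-12))
  expect_error(de_contrast(mod, c(bogus = 1)), "Unknown design column")
  expect_error(de_contrast(mod, c(0, 0)), "all zeros")
})

test_that("result comparison reports strict-inequality fraction and rank stability", {
  set.seed(6)
  a <- tibble::tibble(gene_id = sprintf("g%d", 1:100),
                      p_value = runif(100))
  same <- compare_de_results(a, a)
  expect_equal(same$fraction_smaller_a, 0)
  expect_equal(same$rank_correlation, 1)
  b <- a; b$p_value <- a$p_value^2          # monotone map, all smaller in b
  cmp <- compare_de_results(a, b)
  expect_equal(cmp$fraction_smaller_a, 0)
  expect_equal(cmp$rank_correlation, 1)
  expect_error(compare_de_results(a, a[1:50, ]), "identical gene sets")
})

test_that("adjusting for true artifact factors never costs average power", {
  # the artifact loads genome-wide (as scan-date or degradation artifacts
  # do), so conditioning on it removes residual variance at the tested genes
  grid <- expand.grid(delta = c(0.5, 1), confounded = c(FALSE, TRUE))
  for (i in seq_len(nrow(grid))) {
    pw <- sapply(1:3, function(s) {
      set.seed(900 + 10 * i + s)
      n <- 24; G <- 800
      x <- rep(0:1, each = n / 2)
      f <- if (grid$confounded[i]) 0.3 * x + rnorm(n) else rnorm(n)
      X <- two_group_design(n)
      L <- rnorm(G, 0, 0.7)
      eff <- numeric(G); eff[701:800] <- grid$delta[i]
      e <- mk_expr(L %o% f + eff %o% x + matrix(rnorm(G * n, sd = 0.5), G, n))
      pow <- function(W) {
        de <- de_contrast(moderate(fit_linear_models(e, W)), c(x = 1))
        mean(de$q_value[701:800] < 0.05)
      }
      pow(cbind(X, f = f)) - pow(X)
    })
    expect_gte(mean(pw), -0.02)           # within Monte-Carlo error
  }
})

test_that("a confounded artifact produces false positives only without adjustment", {
  hit <- sapply(1:10, function(s) {
    set.seed(700 + s)
    n <- 20; G <- 500
    x <- rep(0:1, each = 10)
    f <- 0.9 * x + rnorm(n, 0, 0.3)       # artifact tracks the groups
    L <- numeric(G); L[1] <- 3            # strong loading, no true effect
    e <- mk_expr(L %o% f + matrix(rnorm(G * n, sd = 0.5), G, n))
    X <- two_group_design(n)
    de_wo <- de_contrast(moderate(fit_linear_models(e, X)), c(x = 1))
    de_wi <- de_contrast(moderate(fit_linear_models(e, cbind(X, f = f))), c(x = 1))
    c(without = de_wo$p_value[1] < 0.05, with = de_wi$p_value[1] < 0.05)
  })
  expect_gte(sum(hit["without", ]), 9)
  expect_lte(sum(hit["with", ]), 2)
})
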