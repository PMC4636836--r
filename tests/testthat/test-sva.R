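test_that("residualize matches per-gene least squares and centers on intercept", {
  e <- rand_expr(3, 4, seed = 11)
  X <- two_group_design(4)
  r <- residualize(e, X)
  for (g in 1:3) {
    fit <- lm(e[g, ] ~ X - 1)
    expect_equal(unname(r[g, ]), unname(residuals(fit)), tolerance = 1e-10)
  }
  # residuals orthogonal to every design column
  expect_lt(max(abs(r %*% X)), 1e-8)

  r0 <- residualize(e, intercept_design(4))
  expect_lt(max(abs(rowMeans(r0))), 1e-12)

  # design containing the data's only structure -> residuals ~ 0
  x <- rep(0:1, each = 3)
  e2 <- mk_expr((1:5) %o% x + 2)
  expect_lt(max(abs(residualize(e2, two_group_design(6)))), 1e-10)

  bad <- cbind(intercept_design(4), dup = 1)
  expect_error(residualize(e, bad), "rank deficient")
})

test_that("num_sv is invariant to gene order and gene-wise constants", {
  set.seed(21)
  n <- 24; G <- 600
  f <- rnorm(n)
  L <- numeric(G); L[1:150] <- rnorm(150)
  e <- mk_expr(L %o% f + matrix(rnorm(G * n, sd = 0.5), G, n))
  X <- intercept_design(n)
  k0 <- num_sv(e, X, seed = 5)
  e_shuf <- e[sample(G), ]
  expect_identical(num_sv(e_shuf, X, seed = 5), k0)
  e_shift <- e + rnorm(G)           # constant per gene
  expect_identical(num_sv(mk_expr(unclass(e_shift)), X, seed = 5), k0)
})

test_that("a latent factor equal to a protected column is not counted", {
  set.seed(8)
  n <- 30; G <- 800
  x <- rep(0:1, each = n / 2)
  X <- two_group_design(n)
  L <- numeric(G); L[1:240] <- rnorm(240)
  e <- mk_expr(L %o% x + matrix(rnorm(G * n, sd = 0.5), G, n))
  # a tighter level than the default separates "protected factor invisible"
  # from the test's own false-positive rate
  expect_identical(num_sv(e, X, seed = 3, n_permutations = 99, alpha = 0.02), 0L)
  # the same factor is counted when the design does not protect it
  expect_gte(num_sv(e, intercept_design(n), seed = 3,
                    n_permutations = 99, alpha = 0.02), 1L)
})

test_that("num_sv guards its permutation workload and degenerate designs", {
  e <- rand_expr(100, 10, seed = 1)
  expect_error(num_sv(e, intercept_design(10), max_perm_cells = 100), "workload")
  expect_error(num_sv(rand_expr(5, 3, seed = 1),
                      two_group_design(3)), "degrees of freedom")
})

test_that("estimate_svs recovers a planted factor and honors its contracts", {
  set.seed(31)
  n <- 30; G <- 1500
  x <- rep(0:1, each = 15)
  X <- two_group_design(n)
  f <- rnorm(n); f <- f - mean(f)
  L <- numeric(G); L[1:450] <- rnorm(450)
  tr <- numeric(G); tr[1001:1200] <- 2
  e <- mk_expr(L %o% f + tr %o% x + matrix(rnorm(G * n, sd = 0.5), G, n))

  svs <- estimate_svs(e, X, n_sv = 1, seed = 1)
  expect_gt(abs(cor(svs$sv[, 1], f)), 0.95)
  expect_lt(max(abs(crossprod(svs$sv) - diag(1))), 1e-8)
  expect_true(all(svs$gene_weights >= 0 & svs$gene_weights <= 1))
  # genes carrying only the protected effect are down-weighted
  prot_only <- 1001:1200
  prot_only <- prot_only[L[prot_only] == 0]
  expect_lt(median(svs$gene_weights[prot_only]), 0.1)

  expect_error(estimate_svs(e, X, n_sv = n), "between 1 and")
})

test_that("zero iterations reproduce the unweighted residual SVD", {
  e <- rand_expr(200, 16, seed = 4)
  X <- two_group_design(16)
  s0 <- estimate_svs(e, X, n_sv = 2, n_iterations = 0)
  ref <- svd(residualize(e, X), nu = 0, nv = 2)$v
  # equality up to the documented sign convention
  expect_lt(max(abs(abs(crossprod(s0$sv, ref)) - diag(2))), 1e-10)
  expect_true(all(s0$sv[1, ] >= 0))
})

test_that("re-weighting improves recovery of a weak uncorrelated factor", {
  # regime where weighting matters: few loaded genes, strong protected
  # signal on many others that the weights must suppress
  better_or_equal <- sapply(1:10, function(s) {
    set.seed(400 + s)
    n <- 24; G <- 800
    x <- rep(0:1, each = n / 2)
    X <- two_group_design(n)
    f <- residuals(lm(rnorm(n) ~ X - 1))      # factor orthogonal to design
    f <- f / sd(f)
    L <- numeric(G); L[1:80] <- rnorm(80, 0, 0.6)
    tr <- numeric(G); tr[301:600] <- 1.5
    e <- mk_expr(L %o% f + tr %o% x + matrix(rnorm(G * n, sd = 1), G, n))
    a0 <- abs(cor(estimate_svs(e, X, 1, n_iterations = 0)$sv[, 1], f))
    a5 <- abs(cor(estimate_svs(e, X, 1, n_iterations = 5)$sv[, 1], f))
    a5 >= a0 - 1e-6
  })
  expect_gte(sum(better_or_equal), 8)
})

test_that("no surrogate variable aligns with a protected design column", {
  # the data carry both a protected-column factor and a genuine artifact:
  # the single SV must lock onto the artifact, not the protected effect
  aligned <- t(sapply(1:10, function(s) {
    set.seed(500 + s)
    n <- 30; G <- 600
    x <- rep(0:1, each = 15)
    X <- two_group_design(n)
    f <- residuals(lm(rnorm(n) ~ X - 1)); f <- f / sd(f)
    Lx <- numeric(G); Lx[1:180] <- rnorm(180)
    Lf <- numeric(G); Lf[201:380] <- rnorm(180)
    e <- mk_expr(Lx %o% x + Lf %o% f + matrix(rnorm(G * n, sd = 0.5), G, n))
    svs <- estimate_svs(e, X, n_sv = 1, seed = s)
    c(with_x = abs(cor(svs$sv[, 1], x)), with_f = abs(cor(svs$sv[, 1], f)))
  }))
  expect_true(all(aligned[, "with_x"] < 0.3))
  expect_true(all(aligned[, "with_f"] > 0.8))
})

test_that("sv_set wraps external factors and tidiers expose them", {
  m <- matrix(rnorm(20), 10, 2)
  s <- sv_set(m)
  expect_lt(max(abs(crossprod(s$sv) - diag(2))), 1e-10)
  e <- rand_expr(20, 10, seed = 2)
  svs <- estimate_svs(e, intercept_design(10), 2, seed = 1)
  td <- tidy(svs)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 20L)
  expect_equal(glance(svs)$n_sv, 2L)
})
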