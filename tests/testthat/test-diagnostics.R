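test_that("PCA satisfies its variance and orthogonality contracts", {
  set.seed(1)
  # rank-1 matrix: first component carries everything
  u <- rnorm(20); v <- rnorm(6)
  e <- mk_expr(u %o% v)
  p1 <- pca(e, n_components = 3)
  expect_equal(p1$var_explained[1], 1, tolerance = 1e-9)

  e2 <- rand_expr(30, 8, seed = 2)
  p2 <- pca(e2, n_components = 7)
  expect_equal(sum(pca(e2, n_components = 7)$var_explained), 1, tolerance = 1e-9)
  expect_lt(max(abs(crossprod(p2$scores) -
                      diag(diag(crossprod(p2$scores))))), 1e-8)
  expect_true(all(diff(p2$var_explained) <= 1e-12))
  expect_error(pca(e2, n_components = 10), "cannot exceed")
})

test_that("PCA scores match the covariance-eigenvector oracle up to sign", {
  e <- rand_expr(5, 6, seed = 3)
  p <- pca(e, n_components = 4)
  centered <- e - rowMeans(e)
  ev <- eigen(crossprod(centered))       # sample-space covariance (unscaled)
  for (j in 1:4) {
    score_ref <- ev$vectors[, j] * sqrt(ev$values[j])
    expect_equal(abs(unname(p$scores[, j])), abs(score_ref), tolerance = 1e-8)
  }
})

test_that("PCA is invariant to gene-wise constants", {
  e <- rand_expr(25, 7, seed = 4)
  shifted <- e + rnorm(25)
  dimnames(shifted) <- dimnames(e)
  expect_equal(pca(e)$scores, pca(shifted)$scores, tolerance = 1e-9)
})

test_that("PC-covariate association recovers exact and null structure", {
  score <- c(rep(1, 5), rep(5, 5))
  a <- pc_association(score, rep(c("u", "v"), each = 5))
  expect_equal(a$r_squared, 1)
  expect_error(pc_association(score, rep("u", 10)), "at least 2 levels")

  meds <- sapply(1:10, function(s) {
    set.seed(s)
    pc_association(rnorm(60), sample(letters[1:3], 60, TRUE))$r_squared
  })
  expect_lt(median(meds), 0.1)

  # continuous covariate: linear fit
  set.seed(5)
  x <- rnorm(40)
  a2 <- pc_association(2 * x + rnorm(40, 0, 0.01), x)
  expect_gt(a2$r_squared, 0.99)
})

test_that("age smoothing reproduces lines, constants and birth jumps", {
  set.seed(6)
  ages <- c(runif(20, -0.5, -0.17), runif(60, 0.01, 70))
  lin <- 1 + 0.5 * ages
  sm <- age_smooth(lin, ages)
  expect_lt(max(abs(sm$fitted_values - lin)), 1e-6)

  cst <- age_smooth(rep(2, 80), ages)
  expect_lt(max(abs(cst$fitted_values - 2)), 1e-8)

  jumps <- sapply(1:5, function(s) {
    set.seed(s)
    y <- 3 + 2 * (ages > 0) + rnorm(80, 0, 0.5)
    age_smooth(y, ages, birth_offset = TRUE)$jump
  })
  expect_true(all(abs(jumps - 2) < 0.2 * 2))

  expect_error(age_smooth(1:3, c(1, 2)), "must match")
  expect_error(age_smooth(rep(1, 6), c(1, 1, 2, 2, 3, 3)), "4 distinct ages")
})

test_that("the before/after report computes identical stats on identical arms", {
  sim <- simulate_stemcell(stemcell_config(n_genes = 300), seed = 21)
  rep0 <- before_after_report(sim$expr, sim$expr, sim$samples,
                              genes_of_interest = "g00001")
  raw_arm <- dplyr::filter(rep0$associations, arm == "raw")
  cl_arm <- dplyr::filter(rep0$associations, arm == "cleaned")
  expect_equal(raw_arm$r_squared, cl_arm$r_squared)
  expect_equal(rep0$gene_stats$preservation_ratio,
               rep(1, nrow(rep0$gene_stats)))
  expect_error(before_after_report(sim$expr, sim$expr, sim$samples,
                                   genes_of_interest = "nope"), "Unknown gene")
})

test_that("the report captures batch removal and writes valid JSON", {
  sim <- simulate_stemcell(stemcell_config(n_genes = 800), seed = 22)
  X <- build_design(sim$samples, "~ treatment")
  svs <- estimate_svs(sim$expr, X, n_sv = 3, seed = 22)
  cl <- regress_out_svs(sim$expr, X, svs)
  jp <- tempfile(fileext = ".json")
  rp <- before_after_report(sim$expr, cl, sim$samples, json_path = jp)
  assoc <- rp$associations
  pre <- assoc$r_squared[assoc$arm == "raw" & assoc$covariate == "scan_date" &
                           assoc$component == "PC2"]
  post <- assoc$r_squared[assoc$arm == "cleaned" & assoc$covariate == "scan_date" &
                            assoc$component == "PC2"]
  expect_lt(post, pre)
  parsed <- jsonlite::read_json(jp)
  expect_true(all(c("associations", "variance_explained", "mode") %in% names(parsed)))
  expect_equal(length(parsed$associations), nrow(assoc))
})

test_that("a sex gene's group gap collapses under treatment-only cleaning", {
  sim <- simulate_stemcell(stemcell_config(n_genes = 800), seed = 23)
  X <- build_design(sim$samples, "~ treatment")
  k <- num_sv(sim$expr, X, seed = 23)
  svs <- estimate_svs(sim$expr, X, n_sv = max(k, 1), seed = 23)
  cl <- regress_out_svs(sim$expr, X, svs)
  ygene <- sim$truth$gene_truth$gene_id[sim$truth$gene_truth$sex_effect > 0][1]
  rp <- before_after_report(sim$expr, cl, sim$samples, genes_of_interest = ygene)
  sex_row <- dplyr::filter(rp$gene_stats, covariate == "sex")
  expect_lt(sex_row$preservation_ratio, 0.1)
})

test_that("plot constructors return ggplot objects without drawing", {
  sim <- simulate_stemcell(stemcell_config(n_genes = 200), seed = 24)
  p <- pca(sim$expr)
  expect_s3_class(autoplot(p, colour_by = sim$samples$treatment), "ggplot")
  expect_s3_class(plot_pc_covariate(p, sim$samples$scan_date), "ggplot")
  rp <- before_after_report(sim$expr, sim$expr, sim$samples,
                            genes_of_interest = "g00001")
  expect_s3_class(plot_gene(rp, "g00001", colour_by = "sex"), "ggplot")
  expect_s3_class(autoplot(rp), "ggplot")
})
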