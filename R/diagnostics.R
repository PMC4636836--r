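# Exploratory diagnostics: PCA before/after cleaning, PC-covariate
# association statistics, age-trajectory smoothing, and the combined
# before/after report with its machine-readable statistics.

#' Principal component analysis of an expression matrix
#'
#' Genes are row-centered (so adding a constant to any gene changes
#' nothing), then the sample-space principal components are obtained by SVD.
#' Variance-explained fractions are taken over all components, so the
#' returned subset sums to at most 1. The sign of each component is fixed by
#' making its largest-magnitude gene loading positive.
#'
#' @param expr Numeric genes x samples matrix, or a cleaned result.
#' @param n_components Number of components to keep (default
#'   `min(n, G, 10)`).
#' @return An object of class `svclean_pca`: `scores` (n x m, columns
#'   `PC1..PCm`), `loadings` (G x m), `var_explained` (length m).
#' @export
pca <- function(expr, n_components = NULL) {
  expr <- check_expr(expr_values(expr))
  n <- ncol(expr)
  if (n < 2L) abort("PCA needs at least 2 samples.")
  m_max <- min(nrow(expr), n)
  m <- n_components %||% min(m_max, 10L)
  if (m > m_max) abort(sprintf("`n_components` cannot exceed min(G, n) = %d.", m_max))
  centered <- expr - rowMeans(expr)
  sv <- svd(centered)
  total <- sum(sv$d^2)
  flip <- vapply(seq_along(sv$d), function(j) {
    u <- sv$u[, j]
    if (u[which.max(abs(u))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$v, 2L, sv$d * flip, `*`)[, seq_len(m), drop = FALSE]
  loadings <- sweep(sv$u, 2L, flip, `*`)[, seq_len(m), drop = FALSE]
  dimnames(scores) <- list(colnames(expr), paste0("PC", seq_len(m)))
  dimnames(loadings) <- list(rownames(expr), paste0("PC", seq_len(m)))
  structure(list(scores = scores, loadings = loadings,
                 var_explained = (sv$d^2 / total)[seq_len(m)]),
            class = "svclean_pca")
}

#' @export
print.svclean_pca <- function(x, ...) {
  cat(sprintf("<pca> %d components over %d samples; variance explained: %s\n",
              ncol(x$scores), nrow(x$scores),
              paste(sprintf("%.1f%%", 100 * utils::head(x$var_explained, 4)),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname pca
#' @param x An `svclean_pca` object.
#' @param ... Unused.
#' @method tidy svclean_pca
#' @export
tidy.svclean_pca <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "sample_id") %>%
    tidyr::pivot_longer(dplyr::starts_with("PC"),
                        names_to = "component", values_to = "score")
}

#' Association between principal components and a covariate
#'
#' For a categorical covariate, a one-way ANOVA of each PC on the covariate;
#' for a continuous covariate, a simple linear fit. Returns the fraction of
#' PC variance explained (R^2), the F statistic, and its p-value — the
#' numeric counterpart of PC-by-batch boxplots.
#'
#' @param scores n x m score matrix (from [pca()]) or a single score vector.
#' @param covariate Length-n vector, factor/character (categorical, at least
#'   2 levels with at least 2 samples each) or numeric (continuous).
#' @return A tibble with one row per component: `component`, `r_squared`,
#'   `statistic`, `p_value`.
#' @export
pc_association <- function(scores, covariate) {
  if (inherits(scores, "svclean_pca")) scores <- scores$scores
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1L,
                                             dimnames = list(NULL, "PC1"))
  if (length(covariate) != nrow(scores)) {
    abort("`covariate` must have one value per sample.")
  }
  if (!is.numeric(covariate)) {
    f <- factor(covariate)
    if (nlevels(f) < 2L) abort("Categorical covariate needs at least 2 levels.")
    if (any(table(f) < 2L)) abort("Every covariate level needs at least 2 samples.")
    covariate <- f
  }
  purrr::map_dfr(seq_len(ncol(scores)), function(j) {
    fit <- stats::lm(scores[, j] ~ covariate)
    a <- stats::anova(fit)
    tibble::tibble(component = colnames(scores)[j],
                   r_squared = summary(fit)$r.squared,
                   statistic = a$`F value`[1L],
                   p_value = a$`Pr(>F)`[1L])
  })
}

#' Smooth an expression (or PC) trajectory across age
#'
#' Penalized smoothing-spline fit with generalized cross-validation of one
#' value per sample against age. With `birth_offset = TRUE` the fetal and
#' postnatal sides are smoothed separately, allowing a discontinuity at
#' birth (reported as `jump`); there are no samples in the third trimester,
#' so nothing constrains continuity there.
#'
#' @param values Numeric vector, one value per sample.
#' @param ages Ages in years, fetal negative; at least 4 distinct values
#'   (10+ recommended).
#' @param birth_offset Model a discontinuity at birth by smoothing each side
#'   separately.
#' @param grid_length Number of evaluation points for the fitted curve.
#' @return An object of class `svclean_smooth`: `grid` (tibble `age`,
#'   `fitted`), `fitted_values` (at the data ages), `edf` (effective df),
#'   `jump` (fitted discontinuity at birth, or `NA`).
#' @export
age_smooth <- function(values, ages, birth_offset = FALSE, grid_length = 200) {
  if (length(values) != length(ages)) abort("`values` and `ages` must match.")
  if (!all(is.finite(values)) || !all(is.finite(ages))) abort("Inputs must be finite.")
  n_distinct_ages <- length(unique(ages))
  if (n_distinct_ages < 4L) abort("Need at least 4 distinct ages to smooth.")
  fit_side <- function(v, a) {
    # predictions are clamped to the side's data range: splines extrapolate
    # wildly across the third-trimester gap otherwise
    clamp <- function(x) pmin(pmax(x, min(a)), max(a))
    if (length(unique(a)) >= 4L) {
      fit <- stats::smooth.spline(a, v, cv = FALSE)  # GCV; handles tied ages
      list(predict = function(x) stats::predict(fit, clamp(x))$y, edf = fit$df)
    } else {
      fit <- stats::lm(v ~ a)
      list(predict = function(x) unname(stats::predict(fit, data.frame(a = clamp(x)))),
           edf = 2)
    }
  }
  grid <- seq(min(ages), max(ages), length.out = grid_length)
  if (birth_offset) {
    pre <- ages <= 0
    if (!any(pre) || !any(!pre)) {
      abort("`birth_offset = TRUE` needs samples on both sides of birth.")
    }
    f_pre <- fit_side(values[pre], ages[pre])
    f_post <- fit_side(values[!pre], ages[!pre])
    pred <- function(x) ifelse(x <= 0, f_pre$predict(x), f_post$predict(x))
    jump <- f_post$predict(0) - f_pre$predict(0)
    edf <- f_pre$edf + f_post$edf
  } else {
    f <- fit_side(values, ages)
    pred <- f$predict
    jump <- NA_real_
    edf <- f$edf
  }
  structure(list(grid = tibble::tibble(age = grid, fitted = pred(grid)),
                 fitted_values = pred(ages),
                 edf = edf,
                 jump = jump),
            class = "svclean_smooth")
}

#' @export
print.svclean_smooth <- function(x, ...) {
  cat(sprintf("<age smooth> edf %.2f%s\n", x$edf,
              if (is.na(x$jump)) "" else sprintf(", birth jump %.3f", x$jump)))
  invisible(x)
}

# Shared per-arm statistics for the before/after report: identical code path
# for the raw and cleaned arms by construction.
report_arm_stats <- function(expr, samples, covariates, n_components) {
  pc <- pca(expr, n_components = n_components)
  assoc <- purrr::map_dfr(covariates, function(cv) {
    pc_association(pc$scores, samples[[cv]]) %>%
      dplyr::mutate(covariate = cv, .before = 1L)
  })
  list(pca = pc, associations = assoc)
}

#' Before/after cleaning report
#'
#' Computes the exploratory surfaces on the raw and cleaned data with one
#' shared code path per arm: PCA, PC-covariate association statistics for
#' every requested covariate, per-gene group gaps for genes of interest
#' (with the cleaned/raw preservation ratio), and — in lifespan mode —
#' age-smoothed PC trajectories. Figures can be drawn from the result with
#' [autoplot.svclean_report()] / [plot_gene()]; the statistics are always
#' available numerically and can be written as JSON, so figures are never
#' the only record.
#'
#' @param raw Numeric genes x samples matrix.
#' @param cleaned Cleaned result (or matrix) with the same dimensions.
#' @param samples Sample table (one row per sample, matching column order).
#' @param genes_of_interest Optional character vector of gene IDs to
#'   profile; unknown IDs are an error.
#' @param covariates Covariate columns to test against PCs (default: every
#'   column except `sample_id`).
#' @param mode `"stemcell"` (group-structured) or `"lifespan"` (adds
#'   age-smoothed PC trajectories).
#' @param n_components PCs to compute/test (default 4).
#' @param json_path Optional path; when given, the full statistics bundle is
#'   written there as JSON.
#' @return An object of class `svclean_report`: `associations` (tibble with
#'   an `arm` column), `gene_stats`, `pca_raw`, `pca_cleaned`,
#'   `age_smooths` (lifespan mode), `mode`, `samples`, `genes` (per-gene
#'   expression tibble for plotting).
#' @export
before_after_report <- function(raw, cleaned, samples,
                                genes_of_interest = NULL,
                                covariates = NULL,
                                mode = c("stemcell", "lifespan"),
                                n_components = 4, json_path = NULL) {
  mode <- match.arg(mode)
  raw <- check_expr(raw)
  cl <- expr_values(cleaned)
  if (!identical(dim(raw), dim(cl))) abort("raw/cleaned dimensions differ.")
  samples <- tibble::as_tibble(samples)
  covariates <- covariates %||% setdiff(names(samples), "sample_id")
  testable <- vapply(covariates, function(cv) {
    x <- samples[[cv]]
    is.numeric(x) || (nlevels(factor(x)) >= 2L && all(table(factor(x)) >= 2L))
  }, logical(1))
  covariates <- covariates[testable]
  arms <- list(raw = raw, cleaned = cl)
  stats <- purrr::imap(arms, function(e, nm)
    report_arm_stats(e, samples, covariates, n_components))
  associations <- purrr::imap_dfr(stats, function(s, nm)
    dplyr::mutate(s$associations, arm = nm, .before = 1L))

  gene_stats <- NULL
  genes_long <- NULL
  if (!is.null(genes_of_interest)) {
    missing <- setdiff(genes_of_interest, rownames(raw))
    if (length(missing)) {
      abort(sprintf("Unknown gene ID(s): %s", paste(missing, collapse = ", ")))
    }
    cat_covs <- covariates[!vapply(covariates, function(cv)
      is.numeric(samples[[cv]]), logical(1))]
    gene_stats <- purrr::map_dfr(genes_of_interest, function(g) {
      purrr::map_dfr(cat_covs, function(cv) {
        f <- factor(samples[[cv]])
        gap <- function(e) diff(range(tapply(e[g, ], f, mean)))
        tibble::tibble(gene_id = g, covariate = cv,
                       gap_raw = gap(raw), gap_cleaned = gap(cl),
                       preservation_ratio = gap(cl) / gap(raw))
      })
    })
    genes_long <- purrr::imap_dfr(arms, function(e, nm) {
      tibble::as_tibble(t(e[genes_of_interest, , drop = FALSE])) %>%
        dplyr::mutate(sample_id = colnames(e), arm = nm) %>%
        tidyr::pivot_longer(dplyr::all_of(genes_of_interest),
                            names_to = "gene_id", values_to = "expression") %>%
        dplyr::left_join(samples, by = "sample_id")
    })
  }

  age_smooths <- NULL
  if (mode == "lifespan" && "age" %in% names(samples)) {
    age_smooths <- purrr::imap_dfr(stats, function(s, nm) {
      purrr::map_dfr(seq_len(min(4L, ncol(s$pca$scores))), function(j) {
        sm <- age_smooth(s$pca$scores[, j], samples$age, birth_offset = TRUE)
        dplyr::mutate(sm$grid, component = colnames(s$pca$scores)[j], arm = nm)
      })
    })
  }

  report <- structure(list(associations = associations,
                           gene_stats = gene_stats,
                           pca_raw = stats$raw$pca,
                           pca_cleaned = stats$cleaned$pca,
                           age_smooths = age_smooths,
                           mode = mode,
                           samples = samples,
                           genes = genes_long),
                      class = "svclean_report")
  if (!is.null(json_path)) write_report_json(report, json_path)
  report
}

#' Write the numeric content of a report as JSON
#'
#' @param report An `svclean_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  payload <- list(
    mode = report$mode,
    associations = report$associations,
    gene_stats = report$gene_stats,
    variance_explained = list(raw = report$pca_raw$var_explained,
                              cleaned = report$pca_cleaned$var_explained))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' @export
print.svclean_report <- function(x, ...) {
  cat(sprintf("<before/after report> mode '%s'; %d covariate association rows\n",
              x$mode, nrow(x$associations)))
  top <- x$associations %>%
    dplyr::filter(.data$component %in% c("PC1", "PC2")) %>%
    dplyr::arrange(dplyr::desc(.data$r_squared)) %>%
    utils::head(4)
  print(top)
  invisible(x)
}
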