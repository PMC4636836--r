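# Protected ("biological") model construction: translate a declared model
# such as `~ treatment + sex` into a numeric design matrix whose effects are
# preserved during cleaning, including the three lifespan spline models with
# a birth offset.

#' Parse a protected-model formula string
#'
#' Accepts the additive grammar used throughout the package:
#' `~ 1`, `~ treatment`, `~ treatment + sex`, `~ treatment + cnv`,
#' `~ lifespan(A)` (likewise `B`, `C`). Term names other than the
#' `lifespan()` pseudo-term must resolve to sample-table columns; whether a
#' term is coded as categorical indicators or kept as a continuous column is
#' decided by the column's type at build time.
#'
#' @param text Model string, with or without the leading `~`.
#' @return A list of term descriptors with class `svclean_model`.
#' @export
parse_model <- function(text) {
  if (inherits(text, "svclean_model")) return(text)
  if (!is.character(text) || length(text) != 1L) {
    abort("`text` must be a single model string such as \"~ treatment + sex\".")
  }
  rhs <- trimws(sub("^\\s*(expression)?\\s*~", "", text))
  pieces <- trimws(strsplit(rhs, "+", fixed = TRUE)[[1L]])
  pieces <- pieces[pieces != ""]
  terms <- lapply(pieces, function(p) {
    if (p == "1") return(NULL)
    m <- regmatches(p, regexec("^lifespan\\(\\s*([ABC])\\s*\\)$", p))[[1L]]
    if (length(m) == 2L) {
      list(kind = "lifespan", variant = m[2L])
    } else if (grepl("^[A-Za-z_.][A-Za-z0-9_.]*$", p)) {
      list(kind = "column", name = p)
    } else {
      abort(sprintf("Cannot parse model term '%s'.", p))
    }
  })
  terms <- terms[!vapply(terms, is.null, logical(1))]
  structure(list(terms = terms, text = text), class = "svclean_model")
}

#' @export
print.svclean_model <- function(x, ...) {
  cat("<protected model> ", x$text, "\n", sep = "")
  invisible(x)
}

#' Build a protected design matrix from a sample table
#'
#' The intercept is always the first (all-ones) column. Categorical covariates
#' are dummy-coded with the first level in sorted order as the reference;
#' continuous covariates enter as-is; a `lifespan(A|B|C)` term expands to the
#' birth-offset indicator plus the variant's age basis (see
#' [lifespan_design()]), using the sample table's `age` column in years with
#' fetal ages negative.
#'
#' @param samples A sample table (tibble/data.frame) with one row per sample,
#'   in the same order as the expression matrix columns.
#' @param spec A model string or the result of [parse_model()].
#' @return An n x p numeric matrix with labelled columns and attributes
#'   `model_text` (the source formula) and class `svclean_design`.
#' @export
#' @examples
#' st <- tibble::tibble(sample_id = paste0("s", 1:6),
#'                      treatment = rep(c("undifferentiated", "mesendoderm",
#'                                        "neurectoderm"), 2))
#' build_design(st, "~ treatment")
build_design <- function(samples, spec) {
  spec <- parse_model(spec)
  samples <- as.data.frame(samples)
  n <- nrow(samples)
  cols <- list("(Intercept)" = rep(1, n))
  for (term in spec$terms) {
    if (term$kind == "lifespan") {
      if (!"age" %in% names(samples)) {
        abort("lifespan model terms need an 'age' column (years, fetal negative).")
      }
      ld <- lifespan_design(samples$age, term$variant)
      for (j in seq_len(ncol(ld))[-1L]) cols[[colnames(ld)[j]]] <- ld[, j]
    } else {
      nm <- term$name
      if (!nm %in% names(samples)) {
        abort(sprintf("Model term '%s' does not match any sample-table column.", nm))
      }
      x <- samples[[nm]]
      if (is.numeric(x)) {
        if (!all(is.finite(x))) abort(sprintf("Column '%s' has non-finite values.", nm))
        cols[[nm]] <- as.numeric(x)
      } else {
        f <- factor(x)                      # levels sorted; first = reference
        if (nlevels(f) < 1L) abort(sprintf("Column '%s' has no levels.", nm))
        for (lev in levels(f)[-1L]) {
          cols[[paste0(nm, lev)]] <- as.numeric(f == lev)
        }
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  rownames(X) <- if ("sample_id" %in% names(samples)) samples$sample_id else NULL
  if (n < ncol(X)) {
    abort(sprintf("Design has more columns (%d) than samples (%d).", ncol(X), n))
  }
  assert_full_rank(X, arg = "design")
  structure(X, model_text = spec$text, class = c("svclean_design", class(X)))
}

#' B-spline basis (intercept excluded)
#'
#' Evaluates a B-spline basis with the given polynomial degree and interior
#' knots, boundary knots at the data range. The returned basis excludes the
#' intercept, so it has `degree + length(interior_knots)` columns; together
#' with an all-ones column the full basis satisfies the partition of unity
#' (rows sum to 1).
#'
#' @param x Numeric vector of evaluation points (e.g. ages in years).
#' @param degree Polynomial degree, 1 to 3.
#' @param interior_knots Strictly increasing knots strictly inside
#'   `range(x)`.
#' @return A `length(x)` x `(degree + #knots)` basis matrix with values in
#'   \[0, 1\].
#' @export
bspline_basis <- function(x, degree, interior_knots = numeric(0)) {
  if (!all(is.finite(x))) abort("`x` must be finite.")
  if (!degree %in% 1:3) abort("`degree` must be 1, 2 or 3.")
  if (length(interior_knots)) {
    if (is.unsorted(interior_knots, strictly = TRUE)) {
      abort("`interior_knots` must be strictly increasing.")
    }
    if (min(interior_knots) <= min(x) || max(interior_knots) >= max(x)) {
      abort("interior knots must lie strictly inside the data range.")
    }
  }
  B <- splines::bs(x, degree = degree, knots = interior_knots,
                   Boundary.knots = range(x), intercept = FALSE)
  B <- unclass(B)[, , drop = FALSE]
  attr(B, "knots") <- NULL; attr(B, "degree") <- NULL
  attr(B, "Boundary.knots") <- NULL; attr(B, "intercept") <- NULL
  colnames(B) <- paste0("bs", seq_len(ncol(B)))
  B
}

#' Lifespan design matrix with a birth offset
#'
#' Builds the age part of the three lifespan models used to describe brain
#' expression from fetal life through old age. Every variant includes an
#' intercept and a birth-offset indicator `1\{age > 0\}`, which allows an
#' expression-level discontinuity at birth (there are no third-trimester
#' samples to constrain continuity). The age basis is:
#'
#' * **A** — linear spline with a knot at birth: columns `age` and
#'   `max(age, 0)` (2 df).
#' * **B** — degree-2 B-spline with one interior knot at birth (3 df).
#' * **C** — degree-2 B-spline with interior knots at birth and at 1, 10, 20
#'   and 50 years (7 spline columns; 8 age-related df counting the offset).
#'
#' @param ages Numeric ages in years, fetal negative; must span birth.
#' @param variant `"A"`, `"B"` or `"C"`.
#' @return An n x p design matrix (intercept, `birth_offset`, age basis) with
#'   attribute `variant`.
#' @export
lifespan_design <- function(ages, variant = c("A", "B", "C")) {
  variant <- match.arg(variant)
  if (!all(is.finite(ages))) abort("`ages` must be finite.")
  if (!any(ages < 0) || !any(ages > 0)) {
    abort("ages must span birth (some fetal/negative and some postnatal/positive); otherwise the birth offset is confounded with the intercept.")
  }
  offset <- as.numeric(ages > 0)
  basis <- switch(variant,
    A = {
      b <- cbind(age = ages, age_post = pmax(ages, 0))
      b
    },
    B = {
      b <- bspline_basis(ages, degree = 2, interior_knots = 0)
      colnames(b) <- paste0("age_bs", seq_len(ncol(b)))
      b
    },
    C = {
      knots <- c(0, 1, 10, 20, 50)
      if (max(ages) <= max(knots)) {
        abort("variant C needs postnatal ages beyond 50 years (knots at 0, 1, 10, 20, 50).")
      }
      b <- bspline_basis(ages, degree = 2, interior_knots = knots)
      colnames(b) <- paste0("age_bs", seq_len(ncol(b)))
      b
    })
  X <- cbind("(Intercept)" = rep(1, length(ages)), birth_offset = offset, basis)
  # rank is checked where the design is fitted: tiny age sets (e.g. a single
  # fetal sample under variant A) still have well-defined columns
  structure(X, variant = variant,
            model_text = sprintf("~ lifespan(%s)", variant),
            class = c("svclean_design", class(X)))
}

#' Age-related degrees of freedom of a lifespan design
#'
#' Returns the conventional df count for the three lifespan models: the age
#' basis alone for variants A (2) and B (3), and the basis plus the birth
#' offset for variant C (7 + 1 = 8). The offset is part of every model; the
#' counting convention differs by variant and is fixed here so the printed
#' df are unambiguous.
#'
#' @param design A design from [lifespan_design()].
#' @return Integer degrees of freedom.
#' @export
lifespan_df <- function(design) {
  variant <- attr(design, "variant")
  if (is.null(variant)) abort("`design` must come from lifespan_design().")
  n_basis <- ncol(design) - 2L            # minus intercept and birth offset
  as.integer(if (variant == "C") n_basis + 1L else n_basis)
}
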