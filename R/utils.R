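# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||%
#' @importFrom stats rnorm runif setNames
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Validate a genes x samples expression matrix: numeric, finite, unique
# row/column identifiers present.
check_expr <- function(expr, arg = "expr", require_finite = TRUE) {
  if (inherits(expr, "svclean_cleaned")) expr <- expr$values
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort(sprintf("`%s` must be a numeric matrix (genes x samples).", arg))
  }
  if ((nrow(expr) > 0L && is.null(rownames(expr))) ||
      (ncol(expr) > 0L && is.null(colnames(expr)))) {
    abort(sprintf("`%s` must carry gene IDs as rownames and sample IDs as colnames.", arg))
  }
  if (nrow(expr) == 0L && is.null(rownames(expr))) rownames(expr) <- character(0)
  if (anyDuplicated(rownames(expr))) {
    abort(sprintf("`%s` has duplicated gene IDs.", arg))
  }
  if (anyDuplicated(colnames(expr))) {
    abort(sprintf("`%s` has duplicated sample IDs.", arg))
  }
  if (require_finite && !all(is.finite(expr))) {
    abort(sprintf("`%s` contains non-finite values; impute or filter explicitly before use.", arg))
  }
  expr
}

# Validate an n x p design matrix against an expression matrix.
check_design <- function(design, expr = NULL, arg = "design") {
  if (!is.matrix(design) || !is.numeric(design)) {
    abort(sprintf("`%s` must be a numeric design matrix (samples x terms).", arg))
  }
  if (!all(is.finite(design))) abort(sprintf("`%s` contains non-finite values.", arg))
  if (!is.null(expr)) {
    expr <- check_expr(expr)
    if (nrow(design) != ncol(expr)) {
      abort(sprintf("`%s` has %d rows but the expression matrix has %d samples.",
                    arg, nrow(design), ncol(expr)))
    }
  }
  design
}

design_rank <- function(design) qr(design)$rank

assert_full_rank <- function(design, arg = "design") {
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    dropped <- colnames(design)[qd$pivot[seq.int(qd$rank + 1L, ncol(design))]]
    abort(sprintf("`%s` is rank deficient (rank %d < %d columns); offending columns: %s",
                  arg, qd$rank, ncol(design),
                  paste(dropped %||% "<unnamed>", collapse = ", ")))
  }
  invisible(qd)
}

# Extract the numeric matrix from either a plain matrix or a cleaned result.
expr_values <- function(x) {
  if (inherits(x, "svclean_cleaned")) x$values else x
}
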