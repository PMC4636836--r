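# Readers, writers and pre-cleaning normalization for expression matrices
# and sample annotation tables.
#
# Conventions: genes are rows and samples are columns everywhere; values are
# log2-scale intensities; missing values are a hard error at load time.

#' Read a gene-expression matrix
#'
#' Reads a genes x samples matrix of log2 intensities either from a plain
#' tab-delimited file (first column gene/probe IDs, header row of sample IDs)
#' or from the table block of a GEO series-matrix file (the lines between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`; all
#' metadata/characteristics lines are ignored).
#'
#' Malformed input is rejected rather than coerced: ragged rows, duplicated
#' gene IDs, non-numeric or missing values, and absent table markers (for the
#' series-matrix dialect) all raise errors naming the offending line.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` for a plain tab-delimited matrix, `"series_matrix"`
#'   for a GEO series-matrix file.
#' @return A numeric matrix with gene IDs as rownames and sample IDs as
#'   colnames (surrounding quotes stripped).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("probe_id\tS1\tS2", "g1\t1.5\t2.5", "g2\t3\t4"), tf)
#' read_expression_matrix(tf)
read_expression_matrix <- function(path, dialect = c("tsv", "series_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  offset <- 0L
  if (dialect == "series_matrix") {
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) != 1L) {
      abort(sprintf("'%s': missing or duplicated '!series_matrix_table_begin' marker.", path))
    }
    if (length(end) != 1L || end <= begin) {
      abort(sprintf("'%s': missing '!series_matrix_table_end' marker after line %d.", path, begin))
    }
    offset <- begin
    lines <- lines[seq.int(begin + 1L, end - 1L)]
  }
  if (length(lines) < 1L) abort(sprintf("'%s': no table content found.", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != widths[1L])) {
    bad <- which(widths != widths[1L])[1L]
    abort(sprintf("'%s': ragged row at line %d (%d fields, expected %d).",
                  path, bad + offset, widths[bad], widths[1L]))
  }
  strip_quotes <- function(x) gsub('^"|"$', "", x)
  sample_ids <- strip_quotes(fields[[1L]][-1L])
  if (length(lines) == 1L) {
    m <- matrix(numeric(0), nrow = 0L, ncol = length(sample_ids),
                dimnames = list(character(0), sample_ids))
    return(m)
  }
  body <- fields[-1L]
  gene_ids <- strip_quotes(vapply(body, `[[`, character(1), 1L))
  if (anyDuplicated(gene_ids)) {
    dup <- which(duplicated(gene_ids))[1L]
    abort(sprintf("'%s': duplicate gene ID '%s' at line %d.",
                  path, gene_ids[dup], dup + 1L + offset))
  }
  vals <- vapply(body, function(f) {
    suppressWarnings(as.numeric(f[-1L]))
  }, numeric(length(sample_ids)))
  m <- if (length(sample_ids) == 1L) matrix(vals, nrow = length(body), byrow = TRUE) else t(vals)
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1L]
    abort(sprintf("'%s': missing or non-numeric value at line %d (gene '%s').",
                  path, bad + 1L + offset, gene_ids[bad]))
  }
  dimnames(m) <- list(gene_ids, sample_ids)
  m
}

#' Write a gene-expression matrix as TSV
#'
#' Writes the `probe_id`-first tab-delimited format read back losslessly (to
#' 1e-9) by [read_expression_matrix()]. IDs containing tab characters are
#' rejected because they would collide with the delimiter.
#'
#' @param expr Numeric genes x samples matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(expr, path) {
  expr <- check_expr(expr)
  ids <- c(rownames(expr), colnames(expr))
  if (any(grepl("\t", ids, fixed = TRUE))) {
    abort("Gene or sample IDs must not contain tab characters.")
  }
  header <- paste(c("probe_id", colnames(expr)), collapse = "\t")
  if (nrow(expr) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  body <- paste(rownames(expr),
                apply(expr, 1L, function(v) paste(format(v, digits = 15, trim = TRUE,
                                                         scientific = FALSE),
                                                  collapse = "\t")),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Reads a TSV with a required `sample_id` column plus free covariate columns.
#' Column types follow the declared `schema` when given; otherwise columns
#' whose values all parse as numbers become continuous (double) and the rest
#' become categorical (factor). The Unicode minus sign is accepted in numeric
#' columns (fetal ages are conventionally negative).
#'
#' @param path Path to the TSV file.
#' @param schema Optional named character vector mapping column names to
#'   `"categorical"` or `"continuous"`, or the path to a two-column TSV
#'   (`column`, `type`) declaring the same.
#' @return A tibble with `sample_id` first.
#' @export
read_sample_table <- function(path, schema = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "\"")
  if (!"sample_id" %in% names(df)) {
    abort(sprintf("'%s': required column 'sample_id' is absent.", path))
  }
  if (anyDuplicated(df$sample_id)) {
    dup <- df$sample_id[duplicated(df$sample_id)][1L]
    abort(sprintf("'%s': duplicated sample_id '%s'.", path, dup))
  }
  if (is.character(schema) && length(schema) == 1L && is.null(names(schema)) &&
      file.exists(schema)) {
    sdf <- utils::read.delim(schema, sep = "\t", header = TRUE,
                             colClasses = "character")
    schema <- setNames(sdf$type, sdf$column)
  }
  parse_num <- function(x) suppressWarnings(as.numeric(gsub("−", "-", x)))
  out <- lapply(names(df), function(nm) {
    x <- df[[nm]]
    if (nm == "sample_id") return(x)
    declared <- if (!is.null(schema) && nm %in% names(schema)) schema[[nm]] else NA
    num <- parse_num(x)
    if (identical(declared, "continuous") ||
        (is.na(declared) && !anyNA(num) && length(x) > 0L)) {
      if (anyNA(num)) abort(sprintf("'%s': column '%s' declared continuous but not numeric.",
                                    path, nm))
      if (!all(is.finite(num))) abort(sprintf("'%s': column '%s' has non-finite values.",
                                              path, nm))
      num
    } else {
      factor(x)
    }
  })
  names(out) <- names(df)
  tibble::as_tibble(out)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' reference distribution is the row-wise mean of the column-sorted input, and
#' each value is replaced by the reference quantile at its within-column rank.
#' Ties within a column receive the mean of the reference values their ranks
#' span. The operation is idempotent and preserves within-column rank order.
#'
#' @param expr Numeric genes x samples matrix; all values must be finite and
#'   there must be at least two samples.
#' @return The normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(expr) {
  expr <- check_expr(expr)
  if (ncol(expr) < 2L) abort("quantile normalization needs at least 2 samples.")
  if (nrow(expr) < 1L) abort("quantile normalization needs at least 1 gene.")
  sorted <- apply(expr, 2L, sort)
  if (!is.matrix(sorted)) sorted <- matrix(sorted, nrow = 1L)
  ref <- rowMeans(sorted)
  out <- apply(expr, 2L, function(x) {
    r_min <- rank(x, ties.method = "min")
    # mean of the reference values each tie group spans
    grp <- match(x, x)                      # representative index per tie group
    counts <- tabulate(grp, nbins = length(x))
    vapply(seq_along(x), function(i) {
      m <- r_min[i]
      mean(ref[seq.int(m, m + counts[grp[i]] - 1L)])
    }, numeric(1))
  })
  dimnames(out) <- dimnames(expr)
  out
}

#' Log2-transform raw intensities
#'
#' @param expr Numeric genes x samples matrix of raw intensities.
#' @param offset Nonnegative constant added before taking logs; every
#'   `value + offset` must be strictly positive.
#' @return Elementwise `log2(value + offset)`.
#' @export
log2_transform <- function(expr, offset = 0) {
  expr <- check_expr(expr)
  if (!is.numeric(offset) || length(offset) != 1L || offset < 0) {
    abort("`offset` must be a single nonnegative number.")
  }
  shifted <- expr + offset
  if (any(shifted <= 0)) {
    abort("log2 transform undefined: some values are nonpositive after adding the offset.")
  }
  out <- log2(shifted)
  dimnames(out) <- dimnames(expr)
  out
}
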