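# Shared fixture builders: everything is generated in code at test time.

mk_expr <- function(values, nrow = NULL, ncol = NULL) {
  m <- if (is.matrix(values)) values else matrix(values, nrow = nrow, ncol = ncol)
  dimnames(m) <- list(sprintf("g%03d", seq_len(nrow(m))),
                      sprintf("s%03d", seq_len(ncol(m))))
  m
}

rand_expr <- function(G, n, seed = 1, sd = 1, mean = 0) {
  set.seed(seed)
  mk_expr(matrix(rnorm(G * n, mean, sd), G, n))
}

intercept_design <- function(n) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))

two_group_design <- function(n) {
  cbind("(Intercept)" = rep(1, n), x = rep(0:1, each = ceiling(n / 2))[seq_len(n)])
}

# small stem-cell sample table without simulation
toy_samples <- function(n_lines = 2) {
  tidyr::expand_grid(line = sprintf("L%d", seq_len(n_lines)),
                     treatment = c("undifferentiated", "mesendoderm", "neurectoderm"),
                     rep = 1:2) %>%
    dplyr::mutate(line_no = as.integer(sub("L", "", line)),
                  sample_id = paste(line, treatment, rep, sep = "_"),
                  sex = ifelse(line_no %% 2 == 1, "male", "female"),
                  cnv_dosage = (line_no * 2) %% 3) %>%
    dplyr::select(-line_no)
}

write_tsv_matrix <- function(expr, path = tempfile(fileext = ".tsv")) {
  write_expression_matrix(expr, path)
  path
}
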