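# ggplot2 figures for the result types. Every figure has a numeric
# counterpart in the corresponding result object; plots are presentation
# only.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_boxplot geom_line
#'   geom_jitter facet_grid facet_wrap labs theme_bw vars
NULL

#' Plot PCA sample scores
#'
#' @param object An `svclean_pca` result.
#' @param colour_by Optional vector (length n) used to colour samples, e.g.
#'   a treatment or scan-date column.
#' @param components Two component names to draw (default PC1/PC2).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot svclean_pca
#' @export
autoplot.svclean_pca <- function(object, colour_by = NULL,
                                 components = c("PC1", "PC2"), ...) {
  df <- tibble::as_tibble(object$scores, rownames = "sample_id")
  ve <- setNames(object$var_explained, colnames(object$scores))
  lab <- function(pc) sprintf("%s (%.1f%%)", pc, 100 * ve[[pc]])
  p <- ggplot(df, aes(x = .data[[components[1]]], y = .data[[components[2]]]))
  if (!is.null(colour_by)) {
    df$colour_by <- colour_by
    p <- ggplot(df, aes(x = .data[[components[1]]], y = .data[[components[2]]],
                        colour = .data$colour_by)) +
      labs(colour = NULL)
  }
  p + geom_point(size = 2) +
    labs(x = lab(components[1]), y = lab(components[2])) +
    theme_bw()
}

#' Boxplots of a principal component by a categorical covariate
#'
#' The visual counterpart of [pc_association()]: one box per covariate
#' level, e.g. PC2 by scan date.
#'
#' @param pca_result An `svclean_pca`.
#' @param covariate Length-n categorical vector.
#' @param component Component name (default `"PC2"`).
#' @return A ggplot.
#' @export
plot_pc_covariate <- function(pca_result, covariate, component = "PC2") {
  df <- tibble::tibble(score = pca_result$scores[, component],
                       covariate = factor(covariate))
  ggplot(df, aes(x = .data$covariate, y = .data$score)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    labs(x = NULL, y = component) +
    theme_bw()
}

#' Strip plot of one gene by condition, raw versus cleaned
#'
#' @param report An `svclean_report` built with `genes_of_interest`.
#' @param gene_id Gene to draw.
#' @param group_by Sample-table column for the x axis (default
#'   `"treatment"`).
#' @param colour_by Optional sample-table column for colour (e.g. `"sex"`).
#' @return A ggplot faceted by arm (raw | cleaned).
#' @export
plot_gene <- function(report, gene_id, group_by = "treatment", colour_by = NULL) {
  if (is.null(report$genes)) abort("Report was built without `genes_of_interest`.")
  df <- dplyr::filter(report$genes, .data$gene_id == !!gene_id)
  if (nrow(df) == 0L) abort(sprintf("Gene '%s' is not in the report.", gene_id))
  df$arm <- factor(df$arm, levels = c("raw", "cleaned"))
  mapping <- if (is.null(colour_by)) {
    aes(x = .data[[group_by]], y = .data$expression)
  } else {
    aes(x = .data[[group_by]], y = .data$expression, colour = .data[[colour_by]])
  }
  ggplot(df, mapping) +
    geom_jitter(width = 0.15, size = 1.5, alpha = 0.8) +
    facet_wrap(vars(.data$arm)) +
    labs(title = gene_id, x = NULL, y = "log2 expression") +
    theme_bw()
}

#' Age-trajectory panels for the lifespan report
#'
#' PC scores against age in both arms with the fitted smooth overlaid.
#'
#' @param object An `svclean_report` built in lifespan mode.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot svclean_report
#' @export
autoplot.svclean_report <- function(object, ...) {
  if (object$mode == "lifespan" && !is.null(object$age_smooths)) {
    scores <- dplyr::bind_rows(
      raw = tidy(object$pca_raw), cleaned = tidy(object$pca_cleaned),
      .id = "arm")
    scores <- dplyr::left_join(scores, object$samples, by = "sample_id")
    keep <- unique(object$age_smooths$component)
    scores <- dplyr::filter(scores, .data$component %in% keep)
    scores$arm <- factor(scores$arm, levels = c("raw", "cleaned"))
    sm <- object$age_smooths
    sm$arm <- factor(sm$arm, levels = c("raw", "cleaned"))
    ggplot(scores, aes(x = .data$age, y = .data$score)) +
      geom_point(size = 0.8, alpha = 0.5) +
      geom_line(data = sm, aes(x = .data$age, y = .data$fitted),
                colour = "red", linewidth = 0.8) +
      facet_grid(rows = vars(.data$component), cols = vars(.data$arm),
                 scales = "free_y") +
      labs(x = "age (years)", y = "PC score") +
      theme_bw()
  } else {
    assoc <- dplyr::filter(object$associations,
                           .data$component %in% c("PC1", "PC2"))
    assoc$arm <- factor(assoc$arm, levels = c("raw", "cleaned"))
    ggplot(assoc, aes(x = .data$component, y = .data$r_squared,
                      fill = .data$arm)) +
      ggplot2::geom_col(position = "dodge") +
      facet_wrap(vars(.data$covariate)) +
      labs(y = expression(R^2), x = NULL, fill = NULL) +
      theme_bw()
  }
}
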