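#' Plot the variance decomposition of a model suite
#'
#' Stacked variance-ratio bars (one bar per model) from the fitted
#' components, each component divided by its model's phenotypic variance.
#'
#' @param object a `gv_suite`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gv_suite <- function(object, ...) {
  rows <- purrr::map_dfr(names(object$fits), function(code) {
    f <- object$fits[[code]]
    if (!f$converged || sum(f$components) <= 0) return(NULL)
    tibble::tibble(model = code, term = names(f$components),
                   ratio = unname(f$components) / sum(f$components))
  })
  rows$model <- factor(rows$model, levels = object$table$model)
  rows$term <- factor(rows$term, levels = rev(unique(rows$term)))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$model, y = .data$ratio,
                                     fill = .data$term)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "fraction of phenotypic variance",
      fill = NULL,
      title = sprintf("Variance decomposition by model (%s, %s approach)",
                      object$response, object$approach)
    ) +
    ggplot2::theme_minimal()
}

#' Plot predicted additive against epistatic effects
#'
#' Scatterplot of the estimated breeding values (additive BLUPs) against the
#' estimated additive-by-additive epistatic values from one fit, coloured by
#' an optional grouping (e.g. reciprocal cross).
#'
#' @param fit a `gv_fit` with `additive` and `epistatic_aa` terms.
#' @param colour_by optional named vector (by id) used to colour points.
#' @return A ggplot object.
#' @export
plot_blup_scatter <- function(fit, colour_by = NULL) {
  stopifnot(inherits(fit, "gv_fit"))
  need <- c("additive", "epistatic_aa")
  if (!all(need %in% names(fit$blups))) {
    stop("fit lacks additive and/or epistatic_aa terms", call. = FALSE)
  }
  df <- dplyr::inner_join(
    dplyr::rename(fit$blups$additive, ebv = "blup"),
    dplyr::rename(fit$blups$epistatic_aa, eev = "blup"),
    by = "id"
  )
  if (!is.null(colour_by)) df$group <- colour_by[df$id]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ebv, y = .data$eev)) +
    ggplot2::labs(x = "estimated breeding value",
                  y = "estimated epistatic (a x a) value") +
    ggplot2::theme_minimal()
  if (is.null(colour_by)) {
    p + ggplot2::geom_point(alpha = 0.6)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.6)
  }
}

#' Plot per-trait inbreeding depression
#'
#' Bar chart of relative depression `b_R` by trait from a stacked
#' [depression_summary()] table.
#'
#' @param tab tibble of depression summaries with a `trait` column.
#' @return A ggplot object.
#' @export
plot_depression <- function(tab) {
  stopifnot(all(c("trait", "b_r") %in% names(tab)))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$trait, y = .data$b_r)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = expression(b[R]),
                  title = "Relative inbreeding depression by trait") +
    ggplot2::theme_minimal()
}
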