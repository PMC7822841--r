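# ggplot2 displays: the quantile-contrast panel (quantiles left, case
# groups appended right) and the screen's signed variance-explained bars.

#' @describeIn fit_quantile_trend Plot the trend: green quantile points
#'   with 95\% CI bars, blue non-medicated and red medicated case groups
#'   appended beyond the top bin.
#' @param object,x A `quantile_trend`.
#' @param ... Ignored.
#' @export
autoplot.quantile_trend <- function(object, ...) {
  tab <- object$table
  k <- object$k
  tab$xpos <- ifelse(tab$group_type == "quantile", suppressWarnings(as.numeric(tab$group)),
                     k + match(tab$group, object$case_groups %||% character(0)))
  cols <- c(quantile = "#2e7d32", non_medicated = "#1565c0",
            medicated = "#c62828", case = "#6a1b9a")
  tab$colour_key <- ifelse(tab$group_type == "quantile", "quantile", tab$group)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$xpos, y = .data$estimate,
                                    colour = .data$colour_key)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.25) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = cols, guide = "none") +
    ggplot2::labs(x = "PRS quantile (case groups appended right)",
                  y = sprintf("coefficient vs bin %d", object$reference),
                  title = object$trait) +
    ggplot2::theme_minimal()
}

#' @export
plot.quantile_trend <- function(x, ...) print(autoplot.quantile_trend(x, ...))

#' @describeIn prs_screen Bar plot of signed incremental variance
#'   explained (upward for positive, downward for negative associations)
#'   for the top associations.
#' @param object A `prs_screen`.
#' @param top Number of top traits to display.
#' @param ... Ignored.
#' @export
autoplot.prs_screen <- function(object, top = 20, ...) {
  df <- as_tibble(utils::head(object, top))
  df$signed_r2 <- sign(df$beta) * df$r2_incremental
  df$trait <- factor(df$trait, levels = df$trait)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait, y = .data$signed_r2,
                                   fill = .data$signed_r2 > 0)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2e7d32", `FALSE` = "#c62828"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "signed incremental R²") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
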