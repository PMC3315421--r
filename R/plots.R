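#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a standard curve
#'
#' Ct against log10 relative template amount with the fitted line and the
#' implied efficiency in the subtitle.
#'
#' @param object A `standard_curve` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$log10_amount, y = .data$ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope_m,
                         intercept = object$intercept,
                         linetype = "dashed") +
    ggplot2::labs(
      x = "log10 relative template amount", y = "Ct (cycles)",
      title = if (is.na(object$gene_name)) "Standard curve"
              else paste("Standard curve:", object$gene_name),
      subtitle = sprintf("slope %.3f cycles/decade, E = %.3f, R² = %.3f",
                         object$slope_m, object$efficiency,
                         object$r_squared))
}

#' Plot a Ct-Ct regression
#'
#' @param object A `ctct_fit` object.
#' @param ... Unused.
#' @return A ggplot of target Ct against control Ct with the fitted line.
#' @method autoplot ctct_fit
#' @export
autoplot.ctct_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$ct_control, y = .data$ct_target)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope_m,
                         intercept = object$y_intercept,
                         linetype = "dashed") +
    ggplot2::labs(
      x = "control gene Ct (cycles)", y = "target gene Ct (cycles)",
      title = sprintf("Ct-Ct plot [%s]", object$condition),
      subtitle = sprintf("slope %.3f, Y-intercept %.3f, R² = %.3f",
                         object$slope_m, object$y_intercept,
                         object$r_squared))
}

#' Plot a fold-change time course
#'
#' Mean crush/sham fold change per time point with SEM error bars and a
#' reference line at 1 (no change).
#'
#' @param object A `ctct_timecourse` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ctct_timecourse
#' @export
autoplot.ctct_timecourse <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_hr, y = .data$fold_change)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_col(width = 0.8, fill = "grey70", colour = "black") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$fold_change - .data$sem,
                   ymax = .data$fold_change + .data$sem),
      width = 0.2, na.rm = TRUE) +
    ggplot2::labs(x = "time after injury (h)",
                  y = "fold change (crush / sham)",
                  title = "Relative expression time course")
}

#' Volcano plot of a differential-expression result
#'
#' log2 fold change against -log10 p, with the significance and
#' fold-change cutoffs drawn and selected genes highlighted.
#'
#' @param object A `de_result` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(selected = .data$passes_p & .data$passes_fc)
  alpha <- attr(object, "alpha")
  fc <- attr(object, "fold_cutoff")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fc,
                                  y = -log10(pmax(.data$p_value, 1e-300)),
                                  colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-log2(fc), log2(fc)),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "red3"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change (crush - sham)",
                  y = expression(-log[10]~p),
                  title = "Differential expression")
}

#' Group means with SEM bars for an ANOVA fit
#'
#' @param object An `anova_fit` object.
#' @param ... Unused.
#' @return A ggplot of per-group means with SEM error bars; the F test is
#'   reported in the subtitle.
#' @method autoplot anova_fit
#' @export
autoplot.anova_fit <- function(object, ...) {
  g <- object$groups
  ggplot2::ggplot(g, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "black") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::labs(
      x = NULL, y = "group mean ± SEM",
      title = "Group comparison",
      subtitle = sprintf("one-way ANOVA: F(%d,%d) = %.3g, p = %.3g",
                         object$df_between, object$df_within, object$F,
                         object$p_value))
}
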