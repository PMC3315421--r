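#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidy.standard_curve
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(gene_name = x$gene_name, slope_m = x$slope_m,
                 intercept = x$intercept, efficiency = x$efficiency,
                 r_squared = x$r_squared, n_points = x$n_points,
                 efficiency_flag = x$efficiency_flag)
}

#' Tidiers for qPCR fit objects
#'
#' `tidy()` returns the underlying points, `glance()` the one-row fit
#' summary.
#'
#' @param x A `standard_curve`, `ctct_fit` or `anova_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) x$data

#' @rdname tidy.standard_curve
#' @method glance ctct_fit
#' @export
glance.ctct_fit <- function(x, ...) {
  tibble::tibble(condition = x$condition, time_hr = x$time_hr,
                 slope_m = x$slope_m, y_intercept = x$y_intercept,
                 r_squared = x$r_squared, n_pairs = x$n_pairs)
}

#' @rdname tidy.standard_curve
#' @method tidy ctct_fit
#' @export
tidy.ctct_fit <- function(x, ...) x$data

#' @rdname tidy.standard_curve
#' @method glance anova_fit
#' @export
glance.anova_fit <- function(x, ...) {
  tibble::tibble(F = x$F, df_between = x$df_between,
                 df_within = x$df_within, p_value = x$p_value,
                 ms_between = x$ms_between, ms_within = x$ms_within,
                 method = x$method, infinite_f = x$infinite_f)
}

#' @rdname tidy.standard_curve
#' @method tidy anova_fit
#' @export
tidy.anova_fit <- function(x, ...) x$groups

#' @rdname tidy.standard_curve
#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) de_summary(x)
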