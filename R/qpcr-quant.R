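#' Amplification efficiency from a standard-curve slope
#'
#' A serial-dilution standard curve of Ct against log10 template amount has
#' slope m = -1/log10(E), so E = 10^(-1/m). A slope of -3.32 cycles per
#' decade corresponds to perfect doubling (E = 2); shallower (more
#' negative) slopes correspond to lower efficiency.
#'
#' @param slope_m Standard-curve slope in cycles per log10(amount); must be
#'   negative.
#' @return Per-cycle amplification efficiency (> 1).
#' @export
#' @examples
#' efficiency_from_slope(-1 / log10(2)) # 2
#' efficiency_from_slope(-3.52)         # ~1.923
efficiency_from_slope <- function(slope_m) {
  if (!is.numeric(slope_m) || any(!is.finite(slope_m)) || any(slope_m >= 0)) {
    rlang::abort("standard-curve slope must be finite and negative",
                 class = "regenexpr_domain_error")
  }
  10^(-1 / slope_m)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 relative template amount across a
#' dilution series. The slope yields the amplification efficiency via
#' E = 10^(-1/slope); r-squared reports linearity (dilution curves are
#' expected to be linear when efficiency is sample-independent).
#'
#' @param data Data frame with one row per well.
#' @param log10_amount,ct Columns (tidy-eval) holding log10 relative
#'   template amount and the threshold cycle. For a dilution series with
#'   factors 1, 10, 100 the log10 amounts are 0, -1, -2.
#' @param gene_name Label stored in the result.
#' @return Object of class `standard_curve` with fields `slope_m`,
#'   `intercept`, `efficiency`, `r_squared`, `n_points`, `gene_name` and
#'   `efficiency_flag` (TRUE when the implied efficiency exceeds 2.1, a
#'   physically implausible super-doubling usually indicating inhibition or
#'   pipetting error in the series).
#' @export
#' @examples
#' d <- data.frame(x = c(0, 1, 2), ct = c(30, 26.678, 23.356))
#' fit_standard_curve(d, x, ct)
fit_standard_curve <- function(data, log10_amount, ct, gene_name = NA_character_) {
  x <- dplyr::pull(data, {{ log10_amount }})
  y <- dplyr::pull(data, {{ ct }})
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 3) {
    rlang::abort("standard curve needs >= 3 distinct dilution values",
                 class = "regenexpr_insufficient_data")
  }
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    rlang::abort(
      "degenerate standard curve: slope is non-negative, efficiency undefined",
      class = "regenexpr_degenerate_curve")
  }
  eff <- efficiency_from_slope(slope)
  structure(list(
    gene_name = gene_name,
    slope_m = slope,
    intercept = unname(stats::coef(fit)[1]),
    efficiency = eff,
    r_squared = suppressWarnings(summary(fit)$r.squared),
    n_points = length(x),
    efficiency_flag = eff > 2.1,
    data = tibble::tibble(log10_amount = x, ct = y)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "Standard curve%s: slope %.4f cycles/decade, efficiency %.4f, R^2 %.4f (n = %d)\n",
    if (is.na(x$gene_name)) "" else paste0(" [", x$gene_name, "]"),
    x$slope_m, x$efficiency, x$r_squared, x$n_points))
  if (isTRUE(x$efficiency_flag))
    cat("  flag: implied efficiency > 2.1 (check the dilution series)\n")
  invisible(x)
}

#' Fit a Ct-Ct regression for one condition
#'
#' Regresses the target gene's Ct on the control gene's Ct across samples
#' of one condition (ordinary least squares, target on control — the
#' orientation in which the plot is read). When amplification efficiency
#' is sample-independent the points are collinear with slope
#' log(E_control)/log(E_target), and the Y-intercept equals
#' -log10(R)/log10(E_target) where R is the target/control expression
#' ratio; a lower intercept therefore means higher relative expression.
#'
#' @param data Data frame, one row per sample.
#' @param ct_control,ct_target Columns (tidy-eval) with the paired Cts.
#' @param condition,time_hr Annotations stored in the fit.
#' @return Object of class `ctct_fit` with `slope_m`, `y_intercept`,
#'   `r_squared`, `n_pairs` and the annotations. The expression ratio is
#'   derived separately via [ratio_from_intercept()] because it needs the
#'   target efficiency.
#' @export
fit_ctct <- function(data, ct_control, ct_target,
                     condition = NA_character_, time_hr = NA_real_) {
  x <- dplyr::pull(data, {{ ct_control }})
  y <- dplyr::pull(data, {{ ct_target }})
  keep <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    rlang::inform(sprintf("fit_ctct: dropped %d sample(s) with missing Ct",
                          n_dropped))
  }
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) {
    rlang::abort("Ct-Ct fit needs >= 2 samples with finite Ct pairs",
                 class = "regenexpr_insufficient_data")
  }
  if (stats::sd(x) == 0) {
    rlang::abort(paste(
      "all control Cts are identical: slope unidentifiable.",
      "The Ct-Ct method needs input-amount spread across samples."),
      class = "regenexpr_degenerate_fit")
  }
  fit <- stats::lm(y ~ x)
  structure(list(
    condition = condition,
    time_hr = time_hr,
    slope_m = unname(stats::coef(fit)[2]),
    y_intercept = unname(stats::coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    n_pairs = length(x),
    n_dropped = n_dropped,
    data = tibble::tibble(ct_control = x, ct_target = y)
  ), class = "ctct_fit")
}

#' @export
print.ctct_fit <- function(x, ...) {
  cat(sprintf(
    "Ct-Ct fit [%s%s]: slope %.4f, Y-intercept %.4f, R^2 %.4f (n = %d)\n",
    x$condition,
    if (is.na(x$time_hr)) "" else sprintf(", %g h", x$time_hr),
    x$slope_m, x$y_intercept, x$r_squared, x$n_pairs))
  invisible(x)
}

#' Expression ratio from a Ct-Ct intercept
#'
#' Inverts the intercept relation Y = -log(R)/log(E_target):
#' R = E_target^(-Y). An intercept of zero means equal target and control
#' abundance; each cycle of intercept shift at E = 2 corresponds to a
#' 2-fold change in R.
#'
#' @param y_intercept Y-intercept of a Ct-Ct fit (cycles).
#' @param efficiency_target Target-gene amplification efficiency (> 1).
#' @return The relative expression ratio R (> 0).
#' @export
#' @examples
#' ratio_from_intercept(0, 2)             # 1
#' ratio_from_intercept(-1 / log10(2) * log10(10), 2) # 10
ratio_from_intercept <- function(y_intercept, efficiency_target) {
  if (!is.numeric(efficiency_target) || any(efficiency_target <= 1)) {
    rlang::abort("target efficiency must be > 1",
                 class = "regenexpr_domain_error")
  }
  efficiency_target^(-y_intercept)
}

#' Crush-vs-sham fold change from paired Ct-Ct fits
#'
#' The ratio of the two conditions' expression ratios,
#' R_crush / R_sham = E_target^(Yint_sham - Yint_crush). Values above 1
#' mean up-regulation after injury; a one-cycle downward intercept shift
#' at perfect efficiency doubles expression. Swapping the two fits inverts
#' the result.
#'
#' @param fit_crush,fit_sham `ctct_fit` objects for the two conditions at
#'   the same time point.
#' @param efficiency_target Target-gene amplification efficiency (> 1).
#' @return Fold change (scalar, > 0).
#' @export
condition_fold_change <- function(fit_crush, fit_sham, efficiency_target) {
  stopifnot(inherits(fit_crush, "ctct_fit"), inherits(fit_sham, "ctct_fit"))
  t1 <- fit_crush$time_hr; t2 <- fit_sham$time_hr
  if (!(is.na(t1) && is.na(t2)) && !isTRUE(all.equal(t1, t2))) {
    rlang::abort(sprintf(
      "fits are from different time points (%g h vs %g h)", t1, t2),
      class = "regenexpr_pairing_error")
  }
  ratio_from_intercept(fit_crush$y_intercept, efficiency_target) /
    ratio_from_intercept(fit_sham$y_intercept, efficiency_target)
}

#' Time-course fold changes from a Ct table
#'
#' The full Ct-Ct quantification pipeline for an injury time course. For
#' each time point and each replicate sample group, sham and crush Ct-Ct
#' regressions are fitted and the group's crush/sham fold change is taken
#' from the intercept difference; fold changes are then averaged over
#' replicate groups with an SEM (absent when only one group exists). A QC
#' table compares every fitted slope with the expected
#' log(E_control)/log(E_target) and flags deviations above `slope_tol`
#' (slope consistency is the method's internal check that efficiencies are
#' sample-independent).
#'
#' @param ct_table Tibble in the CtTable layout (see [simulate_qpcr()]):
#'   columns sample_id, condition, time_hr, gene_role, gene_name,
#'   replicate, ct. Standard-curve rows (non-empty dilution) are ignored.
#' @param efficiency_target Target-gene efficiency, e.g. from
#'   [fit_standard_curve()].
#' @param efficiency_control Control-gene efficiency (QC only; the fold
#'   change needs only the target efficiency).
#' @param sham,crush Condition labels.
#' @param slope_tol Absolute slope deviation that triggers a QC flag.
#' @return Object of class `ctct_timecourse`: a tibble with one row per
#'   time point (time_hr, n, fold_change, sem) and attributes `fits`
#'   (per-group fit details) and `qc` (slope-consistency table).
#' @export
quantify_timecourse <- function(ct_table,
                                efficiency_target,
                                efficiency_control = efficiency_target,
                                sham = "sham", crush = "crush",
                                slope_tol = 0.1) {
  tbl <- tibble::as_tibble(ct_table)
  need <- c("sample_id", "condition", "time_hr", "gene_role", "replicate", "ct")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    rlang::abort(paste("ct_table is missing column(s):",
                       paste(missing, collapse = ", ")),
                 class = "regenexpr_schema_error")
  }
  if (!"dilution" %in% names(tbl)) tbl$dilution <- NA_real_
  # standard-curve rows (gene_role/condition "standard") are not samples;
  # experimental wells may carry a dilution annotation and pair within it
  wide <- tbl |>
    dplyr::filter(.data$gene_role %in% c("target", "control"),
                  .data$condition != "standard") |>
    dplyr::select("sample_id", "condition", "time_hr", "replicate",
                  "dilution", "gene_role", "ct") |>
    tidyr::pivot_wider(names_from = "gene_role", values_from = "ct",
                       names_prefix = "ct_")

  gaps <- wide |>
    dplyr::distinct(.data$time_hr, .data$condition) |>
    dplyr::count(.data$time_hr) |>
    dplyr::filter(.data$n < 2)
  if (nrow(gaps)) {
    rlang::abort(sprintf(
      "missing a condition at time point(s): %s",
      paste(gaps$time_hr, collapse = ", ")),
      class = "regenexpr_pairing_error")
  }

  expected_slope <- log(efficiency_control) / log(efficiency_target)

  fits <- wide |>
    dplyr::group_by(.data$time_hr, .data$replicate, .data$condition) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::mutate(fit = purrr::pmap(
      list(.data$data, .data$condition, .data$time_hr),
      function(d, cond, t) fit_ctct(d, ct_control, ct_target,
                                    condition = cond, time_hr = t))) |>
    dplyr::mutate(
      slope = purrr::map_dbl(.data$fit, "slope_m"),
      y_intercept = purrr::map_dbl(.data$fit, "y_intercept"),
      r_squared = purrr::map_dbl(.data$fit, "r_squared"),
      n_pairs = purrr::map_int(.data$fit, "n_pairs")
    ) |>
    dplyr::select(-"data")

  qc <- fits |>
    dplyr::transmute(.data$time_hr, .data$replicate, .data$condition,
                     .data$slope, expected_slope = expected_slope,
                     deviation = .data$slope - expected_slope,
                     flagged = abs(.data$slope - expected_slope) > slope_tol)

  per_group <- fits |>
    dplyr::select("time_hr", "replicate", "condition", "y_intercept") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "y_intercept") |>
    dplyr::mutate(fold_change =
                    efficiency_target^(.data[[sham]] - .data[[crush]]))

  out <- per_group |>
    dplyr::group_by(.data$time_hr) |>
    dplyr::summarise(
      n = dplyr::n(),
      sem = sem(.data$fold_change),
      fold_change = mean(.data$fold_change),
      .groups = "drop"
    ) |>
    dplyr::select("time_hr", "n", "fold_change", "sem") |>
    dplyr::arrange(.data$time_hr)

  structure(out, class = c("ctct_timecourse", class(out)),
            fits = fits, qc = qc, per_group = per_group,
            efficiency_target = efficiency_target,
            efficiency_control = efficiency_control)
}

#' Slope-consistency QC table of a time-course result
#'
#' @param x A `ctct_timecourse` object.
#' @return Tibble with one row per fitted Ct-Ct regression: fitted slope,
#'   expected slope log(E_control)/log(E_target), deviation and flag.
#' @export
ctct_qc <- function(x) {
  stopifnot(inherits(x, "ctct_timecourse"))
  attr(x, "qc")
}
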