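#' Net neurite length change from baseline
#'
#' For each measured neurite (cell x neurite class x treatment), subtracts
#' the baseline length from the length at every later time point. Negative
#' values mean retraction. Translation of all lengths of a series by a
#' constant leaves the net change unchanged.
#'
#' @param data Tibble with columns cell_id, neurite_class, treatment,
#'   time_hr, length_um.
#' @param baseline_time Baseline time in hours (default 0).
#' @return Tibble with columns cell_id, neurite_class, treatment, time_hr,
#'   net_change_um for every non-baseline time point.
#' @export
neurite_net_change <- function(data, baseline_time = 0) {
  data <- tibble::as_tibble(data)
  need <- c("cell_id", "neurite_class", "treatment", "time_hr", "length_um")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    rlang::abort(paste("neurite table is missing column(s):",
                       paste(missing, collapse = ", ")),
                 class = "regenexpr_schema_error")
  }
  base <- data |>
    dplyr::filter(.data$time_hr == baseline_time) |>
    dplyr::select("cell_id", "neurite_class", "treatment",
                  baseline_um = "length_um")
  no_base <- dplyr::anti_join(
    dplyr::distinct(data, .data$cell_id, .data$neurite_class, .data$treatment),
    base, by = c("cell_id", "neurite_class", "treatment"))
  if (nrow(no_base)) {
    rlang::abort(sprintf(
      "no baseline (t = %g h) length for cell(s): %s", baseline_time,
      paste(utils::head(no_base$cell_id, 5), collapse = ", ")),
      class = "regenexpr_missing_timepoint")
  }
  data |>
    dplyr::filter(.data$time_hr != baseline_time) |>
    dplyr::inner_join(base, by = c("cell_id", "neurite_class", "treatment")) |>
    dplyr::mutate(net_change_um = .data$length_um - .data$baseline_um) |>
    dplyr::select("cell_id", "neurite_class", "treatment", "time_hr",
                  "net_change_um")
}

# Common constructor for ANOVA results.
new_anova_fit <- function(F, df_between, df_within, p_value,
                          ms_between, ms_within, groups, method,
                          infinite_f = FALSE) {
  structure(list(
    F = F, df_between = df_between, df_within = df_within,
    p_value = p_value, ms_between = ms_between, ms_within = ms_within,
    groups = groups, method = method, infinite_f = infinite_f
  ), class = "anova_fit")
}

#' One-way ANOVA on raw observations
#'
#' Classic fixed-effects one-way decomposition (via `lm`), with the
#' degenerate all-constant case guarded to F = 0, p = 1. For two groups F
#' equals the square of the pooled two-sample t statistic.
#'
#' @param data Tibble of raw observations.
#' @param value,group Columns (tidy-eval) holding the outcome and the group
#'   label.
#' @return Object of class `anova_fit` with F, df_between, df_within,
#'   p_value, ms_between, ms_within and a per-group summary tibble
#'   (group, mean, sd, sem, n).
#' @export
anova_oneway <- function(data, value, group) {
  d <- tibble::tibble(value = dplyr::pull(data, {{ value }}),
                      group = as.character(dplyr::pull(data, {{ group }})))
  d <- dplyr::filter(d, is.finite(.data$value))
  sizes <- table(d$group)
  if (length(sizes) < 2) {
    rlang::abort("one-way ANOVA needs >= 2 groups",
                 class = "regenexpr_insufficient_data")
  }
  if (any(sizes < 2)) {
    rlang::abort(sprintf("every group needs >= 2 values (offending: %s)",
                         paste(names(sizes)[sizes < 2], collapse = ", ")),
                 class = "regenexpr_insufficient_data")
  }
  groups <- d |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     sem = sem(.data$value), n = dplyr::n(), .groups = "drop")
  k <- nrow(groups); N <- nrow(d)
  if (all(groups$sd == 0)) {
    # every group constant: F is 0/0 (guarded to 0) or infinite
    if (length(unique(groups$mean)) == 1) {
      return(new_anova_fit(0, k - 1, N - k, 1, 0, 0, groups, "raw"))
    }
    ssb <- sum(groups$n * (groups$mean - mean(d$value))^2)
    return(new_anova_fit(Inf, k - 1, N - k, 0, ssb / (k - 1), 0, groups,
                         "raw", infinite_f = TRUE))
  }
  tab <- stats::anova(stats::lm(value ~ group, data = d))
  new_anova_fit(tab$`F value`[1], k - 1, N - k, tab$`Pr(>F)`[1],
                tab$`Mean Sq`[1], tab$`Mean Sq`[2], groups, "raw")
}

#' One-way ANOVA from printed summary statistics
#'
#' Reconstructs the one-way F test from per-group (mean, SEM, n) triplets
#' as printed in figures and tables, without access to raw data. The
#' within-group variance of group i is recovered as n_i * sem_i^2 (the SEM
#' convention sd/sqrt(n)); the grand mean is n-weighted. The result is
#' algebraically identical to [anova_oneway()] run on any raw data having
#' exactly those summaries. Because printed means and SEMs are rounded,
#' F values reconstructed from published numbers carry roughly 1-2%
#' rounding propagation.
#'
#' @param summaries Tibble with columns group, mean, sem, n (n >= 2,
#'   sem >= 0, at least one sem > 0).
#' @return An `anova_fit` object (`method = "summary"`). With all SEMs zero
#'   and unequal means the F is infinite and flagged.
#' @export
#' @examples
#' fig <- tibble::tibble(
#'   group = c("CM", "ctrl_siRNA", "siRNA1", "siRNA2"),
#'   mean = c(21.9, 21.2, -1.8, 0.1),
#'   sem = c(3.1, 3.7, 2.9, 1.3),
#'   n = 14)
#' anova_from_summary(fig) # F(3,52) ~ 20.1
anova_from_summary <- function(summaries) {
  s <- tibble::as_tibble(summaries)
  need <- c("group", "mean", "sem", "n")
  missing <- setdiff(need, names(s))
  if (length(missing)) {
    rlang::abort(paste("summary table is missing column(s):",
                       paste(missing, collapse = ", ")),
                 class = "regenexpr_schema_error")
  }
  check_that(nrow(s) >= 2, "summaries", "need >= 2 groups")
  check_that(all(s$n >= 2), "n", "every group needs n >= 2")
  check_that(all(s$sem >= 0), "sem", "SEMs must be >= 0")
  k <- nrow(s); N <- sum(s$n)
  grand <- sum(s$n * s$mean) / N
  ss_between <- sum(s$n * (s$mean - grand)^2)
  ms_between <- ss_between / (k - 1)
  # group variance = n * sem^2; pooled within MS weights by df
  ms_within <- sum((s$n - 1) * s$n * s$sem^2) / sum(s$n - 1)
  groups <- dplyr::mutate(s, sd = .data$sem * sqrt(.data$n)) |>
    dplyr::select("group", "mean", "sd", "sem", "n")
  if (ms_within == 0) {
    if (ms_between == 0)
      return(new_anova_fit(0, k - 1, N - k, 1, 0, 0, groups, "summary"))
    return(new_anova_fit(Inf, k - 1, N - k, 0, ms_between, 0, groups,
                         "summary", infinite_f = TRUE))
  }
  F <- ms_between / ms_within
  new_anova_fit(F, k - 1, N - k,
                stats::pf(F, k - 1, N - k, lower.tail = FALSE),
                ms_between, ms_within, groups, "summary")
}

#' @export
print.anova_fit <- function(x, ...) {
  cat(sprintf("One-way ANOVA (%s data): F(%d,%d) = %s, p = %.3g\n",
              x$method, x$df_between, x$df_within,
              if (is.finite(x$F)) sprintf("%.4g", x$F) else "Inf",
              x$p_value))
  if (x$infinite_f) cat("  flag: zero within-group variance with unequal means\n")
  invisible(x)
}

#' Holm-Sidak step-down adjustment
#'
#' Step-down multiple-comparison procedure controlling family-wise error:
#' p-values are ranked ascending and the i-th smallest is adjusted to
#' max over j <= i of 1 - (1 - p_(j))^(m - j + 1), clipped at 1. Adjusted
#' values are monotone in rank, never below the raw p, and the rejection
#' set is contiguous from the smallest p.
#'
#' @param p Numeric vector of raw p-values in [0, 1].
#' @param alpha Family-wise error rate for the rejection flags.
#' @return Tibble in input order: p, p_adj, reject.
#' @export
holm_sidak <- function(p, alpha = 0.05) {
  check_that(is.numeric(p) && all(p >= 0 & p <= 1), "p",
             "p-values must lie in [0, 1]")
  check_that(alpha > 0 && alpha < 1, "alpha", "must be in (0, 1)")
  m <- length(p)
  ord <- order(p)
  padj_sorted <- cummax(1 - (1 - p[ord])^(m - seq_len(m) + 1))
  padj_sorted <- pmin(padj_sorted, 1)
  p_adj <- numeric(m)
  p_adj[ord] <- padj_sorted
  tibble::tibble(p = p, p_adj = p_adj, reject = p_adj < alpha)
}

#' Pairwise comparisons with Holm-Sidak adjustment
#'
#' All pairwise two-sample comparisons following an omnibus one-way ANOVA,
#' using the pooled within-group mean square as the common error variance
#' (t = (m_i - m_j)/sqrt(MSw (1/n_i + 1/n_j)), df = df_within), with
#' Holm-Sidak family-wise adjustment.
#'
#' @param fit An `anova_fit` object.
#' @param alpha Family-wise error rate.
#' @return Tibble: group1, group2, estimate, t, df, p, p_adj, reject.
#' @export
pairwise_holm_sidak <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "anova_fit"))
  g <- fit$groups
  if (fit$ms_within == 0) {
    rlang::abort("pairwise comparisons undefined with zero within-group variance",
                 class = "regenexpr_degenerate_fit")
  }
  pairs <- utils::combn(seq_len(nrow(g)), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    est <- g$mean[i] - g$mean[j]
    se <- sqrt(fit$ms_within * (1 / g$n[i] + 1 / g$n[j]))
    t <- est / se
    tibble::tibble(group1 = g$group[i], group2 = g$group[j],
                   estimate = est, t = t, df = fit$df_within,
                   p = 2 * stats::pt(-abs(t), fit$df_within))
  })
  adj <- holm_sidak(res$p, alpha = alpha)
  dplyr::mutate(res, p_adj = adj$p_adj, reject = adj$reject)
}

#' Per-group-per-day locomotion summaries
#'
#' Mean, SEM and n of crawled distance (cm per 10 min) for every
#' group x day cell. Cells with a single snail get an NA SEM and a flag.
#'
#' @param data Tibble with columns snail_id, group, day, distance_cm.
#' @return Tibble: group, day, mean, sem, n, sem_defined.
#' @export
#' @examples
#' d <- tibble::tibble(snail_id = 1:3, group = "crush", day = 10,
#'                     distance_cm = c(4, 5, 6))
#' locomotion_summary(d) # mean 5, sem 0.577
locomotion_summary <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("snail_id", "group", "day", "distance_cm")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    rlang::abort(paste("locomotion table is missing column(s):",
                       paste(missing, collapse = ", ")),
                 class = "regenexpr_schema_error")
  }
  out <- data |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::summarise(mean = mean(.data$distance_cm),
                     sem = sem(.data$distance_cm),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(sem_defined = !is.na(.data$sem))
  if (any(!out$sem_defined)) {
    rlang::inform(sprintf(
      "locomotion_summary: %d group-day cell(s) have n < 2 (SEM undefined)",
      sum(!out$sem_defined)))
  }
  out
}
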