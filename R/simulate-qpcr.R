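#' Parameters for the qPCR simulator
#'
#' Bundles the quantities that define a simulated relative-quantification
#' experiment: per-condition true expression ratios, gene-specific
#' amplification efficiencies, the detection threshold, and the noise
#' structure. Defaults reproduce the study conditions of a snail
#' CNS-injury time-course experiment: efficiencies 1.923 (the value a
#' standard-curve slope of -3.52 implies), a crush-vs-sham ratio of 2.35
#' (the 3-hour estimate), and 6 samples per condition.
#'
#' @param R_by_condition Named numeric vector mapping condition to the true
#'   expression ratio R = target abundance / control abundance (> 0).
#' @param E_target,E_control Per-cycle amplification efficiencies, in (1, 2].
#'   E = 2 is perfect doubling.
#' @param threshold_T Detection threshold in arbitrary template units (> 0).
#' @param base_quantity_q0 Mean control-gene template amount (> 0, same units).
#' @param sample_spread_sd SD of log10 per-sample input amount (decades, >= 0).
#'   The Ct-Ct regression needs this spread: with zero spread all control Cts
#'   coincide and the slope is unidentifiable.
#' @param ct_noise_sd SD of additive Gaussian Ct noise (cycles, >= 0).
#' @param n_samples_per_condition Samples per condition per replicate group
#'   (integer >= 2).
#' @param n_groups Independent replicate sample groups (integer >= 1); each
#'   group gets its own samples and its own Ct-Ct fit downstream.
#' @param dilution_series Dilution factors for standard-curve series
#'   (strictly positive, e.g. c(1, 10, 100)).
#' @param measure_dilutions Dilution factors at which every experimental
#'   sample is measured (both genes). The protocol this emulates runs each
#'   sample as a serial dilution — that is what makes the Ct-Ct plot span
#'   several decades and keeps its Y-intercept (a long extrapolation to
#'   Ct_control = 0) well conditioned. Dilution shifts target and control
#'   Ct equally, so it cancels exactly in the Ct-Ct line. Set to 1 for a
#'   single undiluted well per sample.
#' @param target_name,control_name Gene labels used in the output table.
#' @param seed Optional RNG seed.
#' @return A list of class `qpcr_sim_params`.
#' @export
qpcr_sim_params <- function(R_by_condition = c(sham = 1, crush = 2.35),
                            E_target = 1.923,
                            E_control = 1.923,
                            threshold_T = 1e6,
                            base_quantity_q0 = 1,
                            sample_spread_sd = 0.5,
                            ct_noise_sd = 0.3,
                            n_samples_per_condition = 6L,
                            n_groups = 1L,
                            dilution_series = c(1, 10, 100),
                            measure_dilutions = c(1, 10, 1e2, 1e3, 1e4),
                            target_name = "CEBP",
                            control_name = "GAPDH",
                            seed = NULL) {
  check_that(is.numeric(R_by_condition) && length(R_by_condition) >= 1 &&
               !is.null(names(R_by_condition)) && all(nzchar(names(R_by_condition))),
             "R_by_condition", "must be a named numeric vector")
  check_that(all(R_by_condition > 0), "R_by_condition", "ratios must be > 0")
  check_that(is.numeric(E_target) && length(E_target) == 1 &&
               E_target > 1 && E_target <= 2,
             "E_target", "efficiency must lie in (1, 2]")
  check_that(is.numeric(E_control) && length(E_control) == 1 &&
               E_control > 1 && E_control <= 2,
             "E_control", "efficiency must lie in (1, 2]")
  check_that(threshold_T > 0, "threshold_T", "must be > 0")
  check_that(base_quantity_q0 > 0, "base_quantity_q0", "must be > 0")
  check_that(sample_spread_sd >= 0, "sample_spread_sd", "must be >= 0")
  check_that(ct_noise_sd >= 0, "ct_noise_sd", "must be >= 0")
  check_that(n_samples_per_condition >= 2, "n_samples_per_condition",
             "need at least 2 samples per condition")
  check_that(n_groups >= 1, "n_groups", "must be >= 1")
  check_that(all(dilution_series > 0), "dilution_series",
             "dilution factors must be > 0")
  check_that(all(measure_dilutions > 0) && !anyDuplicated(measure_dilutions),
             "measure_dilutions", "must be distinct factors > 0")
  structure(list(
    R_by_condition = R_by_condition,
    E_target = E_target, E_control = E_control,
    threshold_T = threshold_T, base_quantity_q0 = base_quantity_q0,
    sample_spread_sd = sample_spread_sd, ct_noise_sd = ct_noise_sd,
    n_samples_per_condition = as.integer(n_samples_per_condition),
    n_groups = as.integer(n_groups),
    dilution_series = dilution_series,
    measure_dilutions = measure_dilutions,
    target_name = target_name, control_name = control_name,
    seed = seed
  ), class = "qpcr_sim_params")
}

# Deterministic Ct for template amount Q under efficiency E and threshold T:
# the cycle at which Q * E^Ct crosses T.
ct_from_quantity <- function(Q, E, threshold_T) {
  (log10(threshold_T) - log10(Q)) / log10(E)
}

#' Simulate a paired-Ct qPCR dataset
#'
#' Generates target/control threshold-cycle pairs from a shared per-sample
#' input amount. Per sample the input amount is drawn log-normally around
#' `base_quantity_q0`; the control gene gets that amount and the target
#' gene gets R times it; each Ct is the deterministic threshold-crossing
#' cycle plus Gaussian cycle noise. With zero Ct noise the (Ct_control,
#' Ct_target) points lie exactly on a line with slope
#' log(E_control)/log(E_target) and intercept -log10(R)/log10(E_target),
#' which is what the Ct-Ct quantification method exploits.
#'
#' @param params A [qpcr_sim_params()] object.
#' @param time_hr Time-point annotation for the generated records (hours).
#' @return A list of class `qpcr_sim` with elements `ct` (tibble in the
#'   CtTable layout: sample_id, condition, time_hr, gene_role, gene_name,
#'   replicate, ct, dilution) and `truth` (list with the generating R values
#'   and efficiencies). Ground truth is never embedded in the Ct table.
#' @export
#' @examples
#' sim <- simulate_qpcr(qpcr_sim_params(ct_noise_sd = 0, seed = 1))
#' head(sim$ct)
#' sim$truth$R_by_condition
simulate_qpcr <- function(params, time_hr = 0) {
  stopifnot(inherits(params, "qpcr_sim_params"))
  p <- params
  with_seed(p$seed, {
    samples <- tidyr::expand_grid(
      replicate = seq_len(p$n_groups),
      condition = names(p$R_by_condition),
      sample = seq_len(p$n_samples_per_condition)
    )
    # per-sample input amount is shared by both genes and all dilutions
    samples$amount <- p$base_quantity_q0 *
      10^stats::rnorm(nrow(samples), 0, p$sample_spread_sd)
    grid <- tidyr::expand_grid(samples, dilution = p$measure_dilutions)
    n <- nrow(grid)
    R <- unname(p$R_by_condition[grid$condition])
    ct_c <- ct_from_quantity(grid$amount / grid$dilution, p$E_control,
                             p$threshold_T) +
      stats::rnorm(n, 0, p$ct_noise_sd)
    ct_g <- ct_from_quantity(R * grid$amount / grid$dilution, p$E_target,
                             p$threshold_T) +
      stats::rnorm(n, 0, p$ct_noise_sd)
    long <- dplyr::bind_rows(
      dplyr::mutate(grid, gene_role = "control", gene_name = p$control_name,
                    ct = ct_c),
      dplyr::mutate(grid, gene_role = "target", gene_name = p$target_name,
                    ct = ct_g)
    )
    ct_tbl <- long |>
      dplyr::mutate(
        sample_id = sprintf("%s_g%d_s%d", .data$condition, .data$replicate,
                            .data$sample),
        time_hr = time_hr
      ) |>
      dplyr::select("sample_id", "condition", "time_hr", "gene_role",
                    "gene_name", "replicate", "ct", "dilution") |>
      dplyr::arrange(.data$replicate, .data$condition, .data$sample_id,
                     .data$dilution, .data$gene_role)
    truth <- list(
      R_by_condition = p$R_by_condition,
      E_target = p$E_target, E_control = p$E_control,
      time_hr = time_hr
    )
    structure(list(ct = ct_tbl, truth = truth), class = "qpcr_sim")
  })
}

#' Simulate a qPCR time course with sham and crush conditions
#'
#' Convenience wrapper generating one paired-Ct dataset per time point with
#' the sham ratio fixed at 1 and the crush ratio taken from
#' `crush_ratio_by_time`, mirroring an injury time-course design in which
#' each time point has its own sham and crush sample groups. Defaults are
#' the 1/3/5-hour crush-vs-sham ratios 7.36, 2.35 and 1.98.
#'
#' @param crush_ratio_by_time Named numeric vector: names are times in hours,
#'   values the true crush/sham expression ratios.
#' @param params Base [qpcr_sim_params()]; its `R_by_condition` is replaced
#'   per time point, all other settings are reused.
#' @return A `qpcr_sim` list: `ct` is the row-bound CtTable across time
#'   points, `truth` records the per-time ratios and efficiencies.
#' @export
simulate_qpcr_timecourse <- function(crush_ratio_by_time = c("1" = 7.36,
                                                             "3" = 2.35,
                                                             "5" = 1.98),
                                     params = qpcr_sim_params()) {
  stopifnot(inherits(params, "qpcr_sim_params"))
  check_that(!is.null(names(crush_ratio_by_time)) &&
               all(crush_ratio_by_time > 0),
             "crush_ratio_by_time", "must be a named vector of ratios > 0")
  times <- as.numeric(names(crush_ratio_by_time))
  with_seed(params$seed, {
    parts <- purrr::map2(times, unname(crush_ratio_by_time), function(t, r) {
      p <- params
      p$R_by_condition <- c(sham = 1, crush = r)
      p$seed <- NULL # draws come from the surrounding stream
      simulate_qpcr(p, time_hr = t)$ct
    })
    structure(list(
      ct = dplyr::bind_rows(parts),
      truth = list(crush_ratio_by_time = crush_ratio_by_time,
                   E_target = params$E_target, E_control = params$E_control)
    ), class = "qpcr_sim")
  })
}

#' Simulate a standard-curve dilution series
#'
#' Generates Ct values for a serial dilution of one template under a given
#' amplification efficiency. Noise-free output is exactly linear in
#' log10(dilution): Ct rises by 1/log10(E) cycles per 10-fold dilution
#' (3.32 cycles at E = 2), which is the slope the standard-curve fit reads
#' back as m = -1/log10(E).
#'
#' @param efficiency Per-cycle amplification factor in (1, 2].
#' @param dilutions Dilution factors (>= 3 distinct positive values).
#' @param reps Replicate wells per dilution.
#' @param ct_noise_sd SD of Gaussian Ct noise (cycles).
#' @param gene_name Label for the output rows.
#' @param threshold_T,base_quantity_q0 Detection threshold and undiluted
#'   template amount (arbitrary units).
#' @param seed Optional RNG seed.
#' @return Tibble in the CtTable layout with the `dilution` column filled.
#' @export
simulate_standard_curve <- function(efficiency,
                                    dilutions = c(1, 10, 100),
                                    reps = 1L,
                                    ct_noise_sd = 0,
                                    gene_name = "CEBP",
                                    threshold_T = 1e8,
                                    base_quantity_q0 = 1,
                                    seed = NULL) {
  check_that(is.numeric(efficiency) && length(efficiency) == 1 &&
               efficiency > 1 && efficiency <= 2,
             "efficiency", "must lie in (1, 2]")
  check_that(all(dilutions > 0), "dilutions", "must be > 0")
  if (length(unique(dilutions)) < 3) {
    rlang::abort(
      "need at least 3 distinct dilution values (slope unidentifiable otherwise)",
      class = "regenexpr_param_error")
  }
  check_that(reps >= 1, "reps", "must be >= 1")
  check_that(ct_noise_sd >= 0, "ct_noise_sd", "must be >= 0")
  with_seed(seed, {
    grid <- tidyr::expand_grid(dilution = dilutions, replicate = seq_len(reps))
    q <- base_quantity_q0 / grid$dilution
    ct <- ct_from_quantity(q, efficiency, threshold_T) +
      stats::rnorm(nrow(grid), 0, ct_noise_sd)
    tibble::tibble(
      sample_id = sprintf("std_d%g_r%d", grid$dilution, grid$replicate),
      condition = "standard",
      time_hr = NA_real_,
      gene_role = "standard",
      gene_name = gene_name,
      replicate = grid$replicate,
      ct = ct,
      dilution = grid$dilution
    )
  })
}
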