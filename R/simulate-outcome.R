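#' Parameters for the outcome simulator
#'
#' Describes a grouped outcome design — neurite net growth (um) or
#' locomotion distance (cm per 10 min) — as a table of per-group,
#' per-timepoint means and SDs with a common group size. The default
#' design emulates a distal-neurite axotomy experiment: four treatments
#' (conditioned medium, control siRNA, two gene-targeting siRNAs) measured
#' at 10, 24 and 36 hours with n = 14 cells per group, means equal to the
#' reported group means and SDs recovered from the reported SEMs as
#' SEM * sqrt(n).
#'
#' @param design Tibble/data frame with columns `group`, `time`, `mean`,
#'   `sd`. One row per group x timepoint cell.
#' @param n_per_group Observations per group per timepoint (integer >= 2).
#' @param units Unit label carried into the output ("um" or "cm_per_10min").
#' @param seed Optional RNG seed.
#' @return A list of class `outcome_sim_params`.
#' @export
outcome_sim_params <- function(design = default_neurite_design(),
                               n_per_group = 14L,
                               units = "um",
                               seed = NULL) {
  design <- tibble::as_tibble(design)
  need <- c("group", "time", "mean", "sd")
  check_that(all(need %in% names(design)), "design",
             paste("must have columns", paste(need, collapse = ", ")))
  check_that(all(design$sd >= 0), "design", "SDs must be >= 0")
  check_that(!anyDuplicated(design[c("group", "time")]), "design",
             "one row per group x time")
  check_that(n_per_group >= 2, "n_per_group", "must be >= 2")
  structure(list(design = design, n_per_group = as.integer(n_per_group),
                 units = units, seed = seed),
            class = "outcome_sim_params")
}

#' Default distal-neurite outcome design
#'
#' Group means (um net change from baseline) at 10/24/36 h for conditioned
#' medium, control siRNA and two gene-targeting siRNA treatments, with SDs
#' back-computed from reported SEMs at n = 14.
#'
#' @return Tibble with columns group, time, mean, sd.
#' @export
default_neurite_design <- function() {
  n <- 14
  tibble::tribble(
    ~group,          ~time, ~mean, ~sem,
    "CM",              10,  14.2,  2.4,
    "CM",              24,  21.9,  3.1,
    "CM",              36,  29.1,  3.9,
    "control_siRNA",   10,  17.6,  2.7,
    "control_siRNA",   24,  21.2,  3.7,
    "control_siRNA",   36,  24.4,  4.0,
    "cebp_siRNA_1",    10,  -0.3,  3.0,
    "cebp_siRNA_1",    24,  -1.8,  2.9,
    "cebp_siRNA_1",    36,  -5.9,  2.8,
    "cebp_siRNA_2",    10,   1.2,  0.7,
    "cebp_siRNA_2",    24,   0.1,  1.3,
    "cebp_siRNA_2",    36,  -3.0,  2.2
  ) |>
    dplyr::mutate(sd = .data$sem * sqrt(n), .keep = "unused")
}

#' Simulate grouped outcome measurements
#'
#' Draws `n_per_group` Gaussian observations per group x timepoint cell of
#' the design. As n grows the sample mean converges to the design mean and
#' the sample SEM to sd/sqrt(n).
#'
#' @param params An [outcome_sim_params()] object.
#' @return A list of class `outcome_sim`: `data` is a long tibble
#'   (subject_id, group, time, value, units), `truth` echoes the design.
#' @export
#' @examples
#' sim <- simulate_outcomes(outcome_sim_params(seed = 1))
#' dplyr::count(sim$data, group, time)
simulate_outcomes <- function(params) {
  stopifnot(inherits(params, "outcome_sim_params"))
  p <- params
  with_seed(p$seed, {
    data <- p$design |>
      dplyr::rowwise() |>
      dplyr::mutate(value = list(stats::rnorm(p$n_per_group, .data$mean,
                                              .data$sd))) |>
      dplyr::ungroup() |>
      dplyr::select("group", "time", "value") |>
      tidyr::unnest("value") |>
      dplyr::group_by(.data$group, .data$time) |>
      dplyr::mutate(subject_id = sprintf("%s_%02d", .data$group,
                                         dplyr::row_number())) |>
      dplyr::ungroup() |>
      dplyr::mutate(units = p$units) |>
      dplyr::select("subject_id", "group", "time", "value", "units")
    structure(list(data = data,
                   truth = list(design = p$design,
                                n_per_group = p$n_per_group)),
              class = "outcome_sim")
  })
}
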