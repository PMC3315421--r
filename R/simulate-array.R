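#' Parameters for the one-color microarray simulator
#'
#' Defines a spotted one-color array experiment: unique genes, duplicated
#' probe groups, a sham-vs-crush group design, per-array multiplicative
#' scale factors and log-normal intensity noise. Defaults emulate a 15K
#' snail CNS chip: 10,333 unique genes of which 4,425 carry a second probe
#' and 50 technical-control probes are spotted 9 times, hybridized to
#' 4 sham and 4 crush arrays.
#'
#' @param n_unique_probes Number of distinct genes (integer >= 2).
#' @param n_duplicated Genes carrying one extra duplicate probe.
#' @param n_technical Genes spotted `technical_reps` times (technical
#'   replicate controls).
#' @param technical_reps Spot count for technical-control genes.
#' @param n_arrays_per_group Arrays per condition (integer >= 2).
#' @param true_log2_fc Named numeric vector: gene_id -> true log2 fold change
#'   in the crush group. Genes absent from it are null. Gene ids follow the
#'   pattern `gene_00001`, ...
#' @param biological_sd SD of per-spot log2 noise.
#' @param baseline_log2_mean,baseline_log2_sd Mean and SD of per-gene log2
#'   baseline abundance.
#' @param array_scale_factors Optional per-array multiplicative scales
#'   (length 2 * n_arrays_per_group, > 0); by default drawn log-normally
#'   (sdlog 0.2) to emulate between-array intensity differences.
#' @param seed Optional RNG seed.
#' @return A list of class `array_sim_params`.
#' @export
array_sim_params <- function(n_unique_probes = 10333L,
                             n_duplicated = 4425L,
                             n_technical = 50L,
                             technical_reps = 9L,
                             n_arrays_per_group = 4L,
                             true_log2_fc = numeric(0),
                             biological_sd = 0.25,
                             baseline_log2_mean = 8,
                             baseline_log2_sd = 1.5,
                             array_scale_factors = NULL,
                             seed = NULL) {
  check_that(n_unique_probes >= 2, "n_unique_probes", "need >= 2 genes")
  check_that(n_duplicated >= 0 && n_duplicated <= n_unique_probes,
             "n_duplicated", "must be between 0 and n_unique_probes")
  check_that(n_technical >= 0 && n_technical <= n_unique_probes,
             "n_technical", "must be between 0 and n_unique_probes")
  check_that(technical_reps >= 1, "technical_reps", "must be >= 1")
  check_that(n_arrays_per_group >= 2, "n_arrays_per_group",
             "need >= 2 arrays per group for a t-test")
  check_that(biological_sd >= 0, "biological_sd", "must be >= 0")
  if (length(true_log2_fc)) {
    check_that(!is.null(names(true_log2_fc)), "true_log2_fc",
               "must be named by gene id")
    gene_ids <- sprintf("gene_%05d", seq_len(n_unique_probes))
    missing <- setdiff(names(true_log2_fc), gene_ids)
    check_that(length(missing) == 0, "true_log2_fc",
               paste("unknown gene id(s):", paste(missing, collapse = ", ")))
  }
  if (!is.null(array_scale_factors)) {
    check_that(length(array_scale_factors) == 2L * n_arrays_per_group,
               "array_scale_factors", "need one scale per array")
    check_that(all(array_scale_factors > 0), "array_scale_factors",
               "scale factors must be > 0")
  }
  structure(list(
    n_unique_probes = as.integer(n_unique_probes),
    n_duplicated = as.integer(n_duplicated),
    n_technical = as.integer(n_technical),
    technical_reps = as.integer(technical_reps),
    n_arrays_per_group = as.integer(n_arrays_per_group),
    true_log2_fc = true_log2_fc,
    biological_sd = biological_sd,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    array_scale_factors = array_scale_factors,
    seed = seed
  ), class = "array_sim_params")
}

#' Simulate a one-color microarray intensity matrix
#'
#' Probe-level linear intensities are generated as
#' `scale_array * 2^(baseline_gene + effect_gene * is_crush + noise)`,
#' so replicate probes of one gene share the gene-level signal and differ
#' only by independent spot noise, and every array carries its own
#' multiplicative scale that the 75th-percentile normalization must remove.
#'
#' @param params An [array_sim_params()] object.
#' @return A list of class `array_sim`: `matrix` is a tibble with columns
#'   probe_id, gene_id, replicate_group, then one intensity column per array
#'   named `<group>_<i>` (linear scale, attribute `scale = "linear"`);
#'   `truth` holds the regulated genes and the scale factors.
#' @export
#' @examples
#' sim <- simulate_microarray(array_sim_params(
#'   n_unique_probes = 50, n_duplicated = 10, n_technical = 2,
#'   true_log2_fc = c(gene_00001 = 2), seed = 1))
#' dplyr::glimpse(sim$matrix)
simulate_microarray <- function(params) {
  stopifnot(inherits(params, "array_sim_params"))
  p <- params
  with_seed(p$seed, {
    gene_ids <- sprintf("gene_%05d", seq_len(p$n_unique_probes))
    # probe multiplicity: 1 spot each, +1 for duplicated genes, technical
    # controls spotted technical_reps times (these override duplication)
    reps <- rep(1L, p$n_unique_probes)
    if (p$n_duplicated > 0) reps[seq_len(p$n_duplicated)] <- 2L
    if (p$n_technical > 0) {
      tech_idx <- p$n_unique_probes - seq_len(p$n_technical) + 1L
      reps[tech_idx] <- p$technical_reps
    }
    probe_gene <- rep(gene_ids, times = reps)
    probe_id <- sprintf("%s_p%d", probe_gene,
                        unlist(lapply(reps, seq_len), use.names = FALSE))

    arrays <- c(paste0("sham_", seq_len(p$n_arrays_per_group)),
                paste0("crush_", seq_len(p$n_arrays_per_group)))
    scales <- p$array_scale_factors %||% exp(stats::rnorm(length(arrays), 0, 0.2))

    baseline <- stats::rnorm(p$n_unique_probes, p$baseline_log2_mean,
                             p$baseline_log2_sd)
    names(baseline) <- gene_ids
    effect <- stats::setNames(rep(0, p$n_unique_probes), gene_ids)
    if (length(p$true_log2_fc)) effect[names(p$true_log2_fc)] <- p$true_log2_fc

    n_probes <- length(probe_id)
    is_crush <- grepl("^crush_", arrays)
    log2_signal <- outer(baseline[probe_gene], rep(1, length(arrays))) +
      outer(effect[probe_gene], as.numeric(is_crush)) +
      matrix(stats::rnorm(n_probes * length(arrays), 0, p$biological_sd),
             n_probes, length(arrays))
    intensity <- sweep(2^log2_signal, 2, scales, `*`)
    colnames(intensity) <- arrays

    mat <- tibble::tibble(
      probe_id = probe_id,
      gene_id = probe_gene,
      replicate_group = probe_gene
    )
    mat <- dplyr::bind_cols(mat, tibble::as_tibble(intensity))
    attr(mat, "scale") <- "linear"
    truth <- list(
      regulated = tibble::tibble(
        gene_id = names(p$true_log2_fc) %||% character(0),
        true_log2_fc = unname(p$true_log2_fc)
      ),
      array_scale_factors = stats::setNames(scales, arrays),
      biological_sd = p$biological_sd
    )
    structure(list(matrix = mat, truth = truth), class = "array_sim")
  })
}
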