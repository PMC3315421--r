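# Table schemas: required columns and their readr types. Extra columns are
# tolerated (and reported); missing required columns are a schema error.
table_schemas <- list(
  ct = list(
    cols = c(sample_id = "c", condition = "c", time_hr = "d",
             gene_role = "c", gene_name = "c", replicate = "i",
             ct = "d", dilution = "d"),
    delim = ","
  ),
  neurite = list(
    cols = c(cell_id = "c", neurite_class = "c", treatment = "c",
             time_hr = "d", length_um = "d"),
    delim = ","
  ),
  locomotion = list(
    cols = c(snail_id = "c", group = "c", day = "d", distance_cm = "d"),
    delim = ","
  ),
  group_summary = list(
    cols = c(group = "c", mean = "d", sem = "d", n = "i"),
    delim = ","
  )
)

read_schema_table <- function(path, schema_name) {
  sch <- table_schemas[[schema_name]]
  if (is.null(sch)) rlang::abort(paste("unknown schema:", schema_name))
  if (!file.exists(path)) {
    rlang::abort(paste("file not found:", path), class = "regenexpr_io_error")
  }
  header <- names(readr::read_delim(path, delim = sch$delim, n_max = 0,
                                    show_col_types = FALSE))
  missing <- setdiff(names(sch$cols), header)
  if (length(missing)) {
    rlang::abort(sprintf("%s: missing required column(s): %s",
                         path, paste(missing, collapse = ", ")),
                 class = "regenexpr_schema_error")
  }
  extra <- setdiff(header, names(sch$cols))
  if (length(extra)) {
    rlang::inform(sprintf("%s: ignoring extra column(s): %s",
                          path, paste(extra, collapse = ", ")))
  }
  types <- do.call(readr::cols_only,
                   lapply(sch$cols, function(t) switch(
                     t, c = readr::col_character(),
                     d = readr::col_double(),
                     i = readr::col_integer())))
  # parse problems are escalated to errors below; silence readr's warning
  tbl <- suppressWarnings(
    readr::read_delim(path, delim = sch$delim, col_types = types,
                      na = c("", "NA")))
  probs <- readr::problems(tbl)
  if (nrow(probs)) {
    rlang::abort(sprintf(
      "%s: %d unparsable cell(s); first at line %d, column %s",
      path, nrow(probs), probs$row[1] + 1L, probs$col[1]),
      class = "regenexpr_parse_error")
  }
  rlang::inform(sprintf("%s: read %d rows (%s schema)", path, nrow(tbl),
                        schema_name))
  tbl[names(sch$cols)]
}

#' Read a qPCR Ct table
#'
#' CSV with columns sample_id, condition, time_hr, gene_role, gene_name,
#' replicate, ct, dilution (empty for unknowns; standard-curve rows carry
#' a dilution factor). Extra columns are ignored with a message; a missing
#' required column or an unparsable numeric cell is an error.
#'
#' @param path CSV file path.
#' @return Validated tibble in the CtTable layout.
#' @export
read_ct_table <- function(path) read_schema_table(path, "ct")

#' Write a Ct table to CSV
#' @param ct_table CtTable tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct_table, path) {
  readr::write_csv(ct_table, path)
  invisible(path)
}

#' Read a neurite length table
#' @param path CSV with columns cell_id, neurite_class, treatment, time_hr,
#'   length_um.
#' @return Validated tibble.
#' @export
read_neurite_table <- function(path) read_schema_table(path, "neurite")

#' Read a locomotion table
#' @param path CSV with columns snail_id, group, day, distance_cm.
#' @return Validated tibble.
#' @export
read_locomotion_table <- function(path) read_schema_table(path, "locomotion")

#' Read a group-summary table (mean, SEM, n per group)
#' @param path CSV with columns group, mean, sem, n.
#' @return Validated tibble, ready for [anova_from_summary()].
#' @export
read_group_summaries <- function(path) read_schema_table(path, "group_summary")

#' Read an expression matrix TSV
#'
#' Tab-separated with leading columns probe_id, gene_id, replicate_group
#' and one intensity column per array named `<group>_<index>`
#' (e.g. sham_1 ... crush_4), linear scale.
#'
#' @param path TSV file path.
#' @param scale Scale of the stored values ("linear" or "log2").
#' @return Expression tibble with the `scale` attribute set.
#' @export
read_expression_matrix <- function(path, scale = "linear") {
  if (!file.exists(path)) {
    rlang::abort(paste("file not found:", path), class = "regenexpr_io_error")
  }
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("probe_id", "gene_id", "replicate_group")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    rlang::abort(sprintf("%s: missing required column(s): %s",
                         path, paste(missing, collapse = ", ")),
                 class = "regenexpr_schema_error")
  }
  arrays <- setdiff(names(tbl), need)
  if (!length(arrays)) {
    rlang::abort(paste(path, "has no array columns"),
                 class = "regenexpr_schema_error")
  }
  rlang::inform(sprintf("%s: %d probes x %d arrays", path, nrow(tbl),
                        length(arrays)))
  attr(tbl, "scale") <- scale
  tbl
}

#' Write an expression matrix TSV
#' @param mat Expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  readr::write_tsv(mat, path)
  invisible(path)
}

#' Run a configured analysis end to end
#'
#' Dispatches one named command with its parameters, writes every output
#' table under `out_dir`, echoes the resolved configuration to
#' `config_echo.yaml`, and writes `manifest.tsv` listing each artifact with
#' its MD5 hash. Given the same config and seed, outputs are
#' byte-identical. On a stage failure the partial outputs are kept next to
#' a `FAILED` marker file and the error is re-thrown.
#'
#' @param config Named list with elements `command` (one of
#'   "simulate_qpcr", "simulate_array", "simulate_outcome",
#'   "quantify_ctct", "de_run", "stats_anova", "stats_neurite",
#'   "stats_locomotion"), `out_dir`, optional `seed`, and the
#'   command-specific entries documented in the vignette (input paths under
#'   `in_path`, analysis parameters under `params`).
#' @return Invisibly, a character vector of artifact paths.
#' @export
run_pipeline <- function(config) {
  check_that(is.list(config) && !is.null(config$command), "command",
             "config must name a command")
  check_that(!is.null(config$out_dir), "out_dir", "config must set out_dir")
  p <- config$params %||% list()
  if (!is.null(p$alpha)) check_that(p$alpha > 0 && p$alpha < 1, "alpha",
                                    "must be in (0, 1)")
  if (!is.null(p$fold_cutoff)) check_that(p$fold_cutoff >= 1, "fold_cutoff",
                                          "must be >= 1")
  if (grepl("^simulate", config$command) && is.null(config$seed)) {
    rlang::abort("simulation commands require an explicit seed",
                 class = "regenexpr_param_error")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  artifacts <- character(0)
  emit <- function(tbl, file, tsv = FALSE) {
    if (tsv) readr::write_tsv(tbl, out(file)) else readr::write_csv(tbl, out(file))
    artifacts <<- c(artifacts, out(file))
  }
  run <- function() {
    switch(config$command,
      simulate_qpcr = {
        sim <- simulate_qpcr(do.call(qpcr_sim_params,
                                     c(p, list(seed = config$seed))))
        emit(sim$ct, "ct_table.csv")
        yaml::write_yaml(lapply(sim$truth, as.list), out("truth.yaml"))
        artifacts <<- c(artifacts, out("truth.yaml"))
      },
      simulate_array = {
        sim <- simulate_microarray(do.call(array_sim_params,
                                           c(p, list(seed = config$seed))))
        emit(sim$matrix, "expression_matrix.tsv", tsv = TRUE)
        yaml::write_yaml(list(
          regulated = as.list(sim$truth$regulated),
          array_scale_factors = as.list(sim$truth$array_scale_factors)),
          out("truth.yaml"))
        artifacts <<- c(artifacts, out("truth.yaml"))
      },
      simulate_outcome = {
        sim <- simulate_outcomes(do.call(outcome_sim_params,
                                         c(p, list(seed = config$seed))))
        emit(sim$data, "outcomes.csv")
        yaml::write_yaml(list(design = lapply(sim$truth$design, as.vector),
                              n_per_group = sim$truth$n_per_group),
                         out("truth.yaml"))
        artifacts <<- c(artifacts, out("truth.yaml"))
      },
      quantify_ctct = {
        ct <- read_ct_table(config$in_path)
        tc <- quantify_timecourse(
          ct,
          efficiency_target = p$efficiency_target,
          efficiency_control = p$efficiency_control %||% p$efficiency_target)
        emit(tibble::as_tibble(tc), "timecourse.tsv", tsv = TRUE)
        emit(ctct_qc(tc), "ctct_qc.tsv", tsv = TRUE)
      },
      de_run = {
        mat <- read_expression_matrix(config$in_path)
        de <- run_de(mat, alpha = p$alpha %||% 0.05,
                     fold_cutoff = p$fold_cutoff %||% 2.0,
                     q = p$q %||% 75)
        emit(tibble::as_tibble(de), "de_results.tsv", tsv = TRUE)
        emit(de_summary(de), "de_summary.tsv", tsv = TRUE)
      },
      stats_anova = {
        s <- read_group_summaries(config$in_path)
        fit <- anova_from_summary(s)
        emit(glance(fit), "anova.tsv", tsv = TRUE)
        emit(pairwise_holm_sidak(fit, alpha = p$alpha %||% 0.05),
             "pairwise.tsv", tsv = TRUE)
      },
      stats_neurite = {
        d <- read_neurite_table(config$in_path)
        net <- neurite_net_change(d, baseline_time = p$baseline_time %||% 0)
        emit(net, "net_change.csv")
        groups <- net |>
          dplyr::group_by(.data$neurite_class, .data$treatment,
                          .data$time_hr) |>
          dplyr::summarise(mean = mean(.data$net_change_um),
                           sem = sem(.data$net_change_um),
                           n = dplyr::n(), .groups = "drop")
        emit(groups, "net_change_summary.csv")
      },
      stats_locomotion = {
        d <- read_locomotion_table(config$in_path)
        emit(locomotion_summary(d), "locomotion_summary.csv")
      },
      rlang::abort(paste("unknown command:", config$command),
                   class = "regenexpr_param_error")
    )
  }
  status <- tryCatch({ run(); "ok" }, error = function(e) {
    writeLines(conditionMessage(e), out("FAILED"))
    stop(e)
  })
  yaml::write_yaml(config, out("config_echo.yaml"))
  artifacts <- c(artifacts, out("config_echo.yaml"))
  manifest <- tibble::tibble(
    artifact = basename(artifacts),
    md5 = unname(tools::md5sum(artifacts)),
    package_version = as.character(utils::packageVersion("regenexpr"))
  )
  readr::write_tsv(manifest, out("manifest.tsv"))
  rlang::inform(sprintf("run_pipeline[%s]: wrote %d artifact(s) to %s",
                        config$command, length(artifacts), config$out_dir))
  invisible(artifacts)
}
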