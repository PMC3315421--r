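# Column names of the intensity (array) columns of an expression tibble.
array_columns <- function(mat) {
  setdiff(names(mat), c("probe_id", "gene_id", "replicate_group"))
}

# Group factor parsed from array column names "<group>_<i>".
array_groups <- function(arrays) sub("_[0-9]+$", "", arrays)

#' Percentile-normalize a one-color intensity matrix
#'
#' Divides each array (column) by its own q-th percentile so arrays become
#' comparable despite different overall brightness; after scaling, every
#' array's q-th percentile is exactly 1. By default the scaled values are
#' then log2-transformed (the scale on which downstream tests run), giving
#' each array a q-th percentile of 0. Percentiles use the linear
#' interpolation between order statistics (R's default quantile type 7).
#'
#' @param mat Expression tibble: columns probe_id, gene_id, replicate_group
#'   and one positive linear-scale intensity column per array.
#' @param q Percentile in (0, 100); 75 is the convention for one-color
#'   arrays.
#' @param log2_transform Apply log2 after scaling (default TRUE).
#' @return The normalized tibble, attribute `scale` set to "log2" or
#'   "linear".
#' @export
percentile_normalize <- function(mat, q = 75, log2_transform = TRUE) {
  mat <- tibble::as_tibble(mat)
  check_that(q > 0 && q < 100, "q", "percentile must be in (0, 100)")
  arrays <- array_columns(mat)
  if (identical(attr(mat, "scale"), "log2")) {
    rlang::abort("matrix is already log2-scale; normalization needs linear intensities",
                 class = "regenexpr_scale_error")
  }
  for (a in arrays) {
    v <- mat[[a]]
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad)) {
      rlang::abort(sprintf(
        "non-positive intensity in array %s at probe(s): %s", a,
        paste(utils::head(mat$probe_id[bad], 5), collapse = ", ")),
        class = "regenexpr_intensity_error")
    }
    v <- v / stats::quantile(v, q / 100, names = FALSE, type = 7)
    mat[[a]] <- if (log2_transform) log2(v) else v
  }
  attr(mat, "scale") <- if (log2_transform) "log2" else "linear"
  mat
}

#' Collapse replicate probes to gene level
#'
#' Replaces each replicate-probe group by its per-array median, the
#' standard summary for duplicated spots. Groups of size 1 pass through
#' unchanged; output has one row per distinct replicate group.
#'
#' @param mat Log2-scale expression tibble with a `replicate_group` column.
#' @return Gene-level tibble (gene_id = replicate group, one row each).
#' @export
collapse_replicate_probes <- function(mat) {
  mat <- tibble::as_tibble(mat)
  if (!"replicate_group" %in% names(mat) ||
      anyNA(mat$replicate_group) || any(!nzchar(mat$replicate_group))) {
    rlang::abort("every probe needs a replicate_group assignment",
                 class = "regenexpr_schema_error")
  }
  arrays <- array_columns(mat)
  out <- mat |>
    dplyr::group_by(gene_id = .data$replicate_group) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(arrays), stats::median),
                     .groups = "drop")
  attr(out, "scale") <- attr(mat, "scale")
  out
}

#' Equal-variance two-sample t-test for one gene
#'
#' Two-sided unpaired Student t-test on log2 values with pooled variance
#' and df = n1 + n2 - 2. Degenerate inputs are guarded: zero pooled
#' variance with equal means gives t = 0, p = 1; zero pooled variance with
#' unequal means gives p -> 0 with a degeneracy flag.
#'
#' @param values_sham,values_crush Numeric vectors (>= 2 finite values each).
#' @return Tibble with columns t, df, p, degenerate. t is signed
#'   crush - sham.
#' @export
gene_ttest <- function(values_sham, values_crush) {
  x <- values_sham[is.finite(values_sham)]
  y <- values_crush[is.finite(values_crush)]
  if (length(x) < 2 || length(y) < 2) {
    rlang::abort("t-test needs >= 2 finite values per group",
                 class = "regenexpr_insufficient_data")
  }
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  diff <- mean(y) - mean(x)
  if (sp2 == 0) {
    if (diff == 0) return(tibble::tibble(t = 0, df = df, p = 1,
                                         degenerate = FALSE))
    return(tibble::tibble(t = sign(diff) * Inf, df = df, p = 0,
                          degenerate = TRUE))
  }
  t <- diff / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble::tibble(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
                 degenerate = FALSE)
}

# Vectorized row-wise Student t-test: X, Y matrices (genes x arrays).
row_ttest <- function(X, Y) {
  n1 <- ncol(X); n2 <- ncol(Y)
  df <- n1 + n2 - 2
  m1 <- rowMeans(X); m2 <- rowMeans(Y)
  v1 <- rowSums((X - m1)^2) / (n1 - 1)
  v2 <- rowSums((Y - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  t <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  degen <- sp2 == 0
  t[degen & (m2 == m1)] <- 0
  p <- 2 * stats::pt(-abs(t), df)
  p[degen & (m2 == m1)] <- 1
  p[degen & (m2 != m1)] <- 0
  list(t = t, df = df, p = p, mean_sham = m1, mean_crush = m2,
       degenerate = degen & (m2 != m1))
}

#' One-color differential-expression pipeline
#'
#' The fixed pipeline for a sham-vs-crush one-color design:
#' percentile-normalize (linear input) -> log2 -> collapse replicate
#' probes by median -> per-gene equal-variance Student t-test -> p-value
#' and fold-change filters. Fold change is 2^(mean_log2_crush -
#' mean_log2_sham), reported both as the log2 difference and in the signed
#' convention (-2 means 2-fold down). Benjamini-Hochberg q-values are
#' added for context only; the selection filters use raw p-values.
#'
#' @param mat Expression tibble, linear scale (probe level) or log2 scale
#'   (already normalized); probe-level input is normalized and collapsed.
#' @param alpha Raw p-value cutoff (default 0.05).
#' @param fold_cutoff Fold-change cutoff on the linear scale (default 2).
#' @param q Normalization percentile (default 75).
#' @return Object of class `de_result`: per-gene tibble ranked by p with
#'   columns gene_id, mean_log2_sham, mean_log2_crush, log2_fc,
#'   fold_change_signed, t_statistic, df, p_value, q_value, passes_p,
#'   passes_fc, direction; attribute `summary` holds the count summary
#'   (see [de_summary()]).
#' @export
run_de <- function(mat, alpha = 0.05, fold_cutoff = 2.0, q = 75) {
  check_that(alpha > 0 && alpha < 1, "alpha", "must be in (0, 1)")
  check_that(fold_cutoff >= 1, "fold_cutoff", "must be >= 1")
  mat <- tibble::as_tibble(mat)
  if (!identical(attr(mat, "scale"), "log2")) {
    mat <- percentile_normalize(mat, q = q, log2_transform = TRUE)
  }
  if ("replicate_group" %in% names(mat)) {
    mat <- collapse_replicate_probes(mat)
  }
  arrays <- array_columns(mat)
  groups <- array_groups(arrays)
  if (!all(c("sham", "crush") %in% groups)) {
    rlang::abort("need both sham and crush arrays",
                 class = "regenexpr_design_error")
  }
  if (any(table(groups) < 2)) {
    rlang::abort("each group needs >= 2 arrays for a t-test",
                 class = "regenexpr_design_error")
  }
  X <- as.matrix(mat[arrays[groups == "sham"]])
  Y <- as.matrix(mat[arrays[groups == "crush"]])
  tt <- row_ttest(X, Y)
  res <- tibble::tibble(
    gene_id = mat$gene_id,
    mean_log2_sham = tt$mean_sham,
    mean_log2_crush = tt$mean_crush,
    log2_fc = tt$mean_crush - tt$mean_sham,
    t_statistic = tt$t,
    df = tt$df,
    p_value = tt$p,
    degenerate = tt$degenerate
  ) |>
    dplyr::mutate(
      fold_change_signed = sign(.data$log2_fc) * 2^abs(.data$log2_fc),
      q_value = stats::p.adjust(.data$p_value, "BH"),
      passes_p = .data$p_value < alpha,
      passes_fc = abs(.data$log2_fc) >= log2(fold_cutoff),
      direction = dplyr::case_when(.data$log2_fc > 0 ~ "up",
                                   .data$log2_fc < 0 ~ "down",
                                   TRUE ~ "none")
    ) |>
    dplyr::arrange(.data$p_value) |>
    dplyr::select("gene_id", "mean_log2_sham", "mean_log2_crush", "log2_fc",
                  "fold_change_signed", "t_statistic", "df", "p_value",
                  "q_value", "passes_p", "passes_fc", "direction",
                  "degenerate")
  n_sig <- sum(res$passes_p)
  n_up <- sum(res$passes_p & res$passes_fc & res$log2_fc > 0)
  n_down <- sum(res$passes_p & res$passes_fc & res$log2_fc < 0)
  summary <- de_summary_from_counts(n_tested = nrow(res),
                                    n_significant = n_sig,
                                    n_up = n_up, n_down = n_down)
  structure(res, class = c("de_result", class(res)),
            summary = summary, alpha = alpha, fold_cutoff = fold_cutoff)
}

#' Regulated-gene count summary
#'
#' Builds the standard count breakdown of a DE run from its four counts:
#' how many genes changed significantly at all, how many of those crossed
#' the fold-change cutoff (split up/down), and the corresponding
#' percentages of the significant set. Percentages are left unrounded;
#' for display, round half-up to the printed precision (see
#' [round_half_up()]).
#'
#' @param n_tested,n_significant,n_up,n_down Counts: genes tested,
#'   significant at the p cutoff, and significant-and-above-cutoff up/down.
#' @return One-row tibble with the counts, n_fc = n_up + n_down,
#'   and pct_fc_of_significant, pct_up_of_significant,
#'   pct_down_of_significant, pct_lt_fc_of_significant.
#' @export
#' @examples
#' s <- de_summary_from_counts(10333, 348, 42, 25)
#' s$n_fc                                   # 67
#' round_half_up(s$pct_fc_of_significant, 1) # 19.3
de_summary_from_counts <- function(n_tested, n_significant, n_up, n_down) {
  check_that(n_significant <= n_tested, "n_significant",
             "cannot exceed n_tested")
  check_that(n_up + n_down <= n_significant, "n_up",
             "n_up + n_down cannot exceed n_significant")
  n_fc <- n_up + n_down
  pct <- function(k) if (n_significant > 0) 100 * k / n_significant else NA_real_
  tibble::tibble(
    n_tested = n_tested, n_significant = n_significant,
    n_fc = n_fc, n_up = n_up, n_down = n_down,
    pct_fc_of_significant = pct(n_fc),
    pct_up_of_significant = pct(n_up),
    pct_down_of_significant = pct(n_down),
    pct_lt_fc_of_significant = pct(n_significant - n_fc)
  )
}

#' Count summary of a DE result
#'
#' @param x A `de_result` object from [run_de()].
#' @return The one-row summary tibble (see [de_summary_from_counts()]).
#' @export
de_summary <- function(x) {
  stopifnot(inherits(x, "de_result"))
  attr(x, "summary")
}

#' Hierarchical clustering for heat-map gene ordering
#'
#' Agglomerative clustering of genes on Pearson-correlation distance
#' (1 - r across arrays) with average linkage — the conventional ordering
#' for expression heat maps. Genes with zero variance have no defined
#' correlation; their distance to every other gene is set to 1 (maximal
#' dissimilarity under this metric's null) and a message reports them.
#'
#' @param mat Log2-scale gene-level expression tibble (>= 2 genes), or a
#'   plain numeric matrix with genes as rows and rownames as labels.
#' @return Object of class `cluster_ordering`: list with `merge`, `height`,
#'   `order` (leaf order as a permutation of input genes), `labels`,
#'   `metric`, `linkage` and the underlying `hclust` object.
#' @export
hierarchical_cluster <- function(mat) {
  if (is.data.frame(mat)) {
    labels <- mat$gene_id %||% mat$probe_id
    m <- as.matrix(mat[array_columns(tibble::as_tibble(mat))])
    rownames(m) <- labels
  } else {
    m <- as.matrix(mat)
    labels <- rownames(m) %||% as.character(seq_len(nrow(m)))
    rownames(m) <- labels
  }
  if (nrow(m) < 2) {
    rlang::abort("clustering needs >= 2 genes",
                 class = "regenexpr_insufficient_data")
  }
  d <- correlation_distance(m)
  hc <- stats::hclust(d, method = "average")
  structure(list(
    merge = hc$merge, height = hc$height, order = hc$order,
    labels = labels, metric = "pearson", linkage = "average",
    hclust = hc
  ), class = "cluster_ordering")
}

# 1 - Pearson correlation distance with the zero-variance rule.
correlation_distance <- function(m) {
  sds <- apply(m, 1, stats::sd)
  zero_var <- sds == 0 | !is.finite(sds)
  if (any(zero_var)) {
    rlang::inform(sprintf(
      "correlation distance: %d zero-variance gene(s) set to maximal dissimilarity (1): %s",
      sum(zero_var),
      paste(utils::head(rownames(m)[zero_var], 5), collapse = ", ")))
  }
  r <- suppressWarnings(stats::cor(t(m)))
  d <- 1 - r
  d[!is.finite(d)] <- 1
  if (any(zero_var)) {
    d[zero_var, ] <- 1
    d[, zero_var] <- 1
  }
  diag(d) <- 0
  stats::as.dist(d)
}

#' Newick serialization of a gene cluster tree
#'
#' @param x A `cluster_ordering` object.
#' @param path Optional file path; when given the tree is written there.
#' @return The Newick string, invisibly when written to a file.
#' @export
cluster_newick <- function(x, path = NULL) {
  stopifnot(inherits(x, "cluster_ordering"))
  phy <- ape::as.phylo(x$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @export
print.cluster_ordering <- function(x, ...) {
  cat(sprintf("Gene cluster ordering: %d leaves, %s distance, %s linkage\n",
              length(x$labels), x$metric, x$linkage))
  cat("leaf order:", paste(utils::head(x$labels[x$order], 10), collapse = ", "),
      if (length(x$labels) > 10) "..." else "", "\n")
  invisible(x)
}
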