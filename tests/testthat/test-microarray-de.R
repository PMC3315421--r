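test_that("percentile normalization scales every array to percentile 1", {
  m <- tiny_expression_matrix()
  norm <- percentile_normalize(m, log2_transform = FALSE)
  arrays <- c("sham_1", "sham_2", "crush_1", "crush_2")
  for (a in arrays) {
    expect_equal(stats::quantile(norm[[a]], 0.75, names = FALSE), 1,
                 tolerance = 1e-12)
  }
  # scale invariance: arrays that are scalar multiples become identical
  expect_equal(norm$sham_1, norm$sham_2, tolerance = 1e-12)
  # log2 output has percentile 0 (9 probes: the 75th percentile sits on an
  # order statistic, so log and interpolation commute)
  m9 <- tibble::tibble(probe_id = sprintf("p%d", 1:9),
                       gene_id = sprintf("g%d", 1:9),
                       replicate_group = sprintf("g%d", 1:9),
                       sham_1 = c(1, 2, 4, 8, 16, 32, 64, 128, 256),
                       crush_1 = 2^(9:1))
  attr(m9, "scale") <- "linear"
  norm2 <- percentile_normalize(m9)
  expect_equal(stats::quantile(norm2$sham_1, 0.75, names = FALSE), 0,
               tolerance = 1e-12)
  expect_equal(stats::quantile(norm2$crush_1, 0.75, names = FALSE), 0,
               tolerance = 1e-12)

  # constant array: all values become 1 (0 on the log scale)
  m$sham_1 <- rep(8, 4)
  expect_equal(percentile_normalize(m, log2_transform = FALSE)$sham_1,
               rep(1, 4))

  # random matrices against the sort-based percentile oracle
  set.seed(51)
  for (i in 1:5) {
    v <- rlnorm(37, 6, 1)
    q <- sample(c(25, 50, 75, 90), 1)
    expect_equal(stats::quantile(v, q / 100, names = FALSE, type = 7),
                 percentile_oracle(v, q), tolerance = 1e-12)
    mm <- tibble::tibble(probe_id = sprintf("p%d", 1:37),
                         gene_id = sprintf("g%d", 1:37),
                         replicate_group = sprintf("g%d", 1:37),
                         sham_1 = v, crush_1 = rlnorm(37, 6, 1))
    attr(mm, "scale") <- "linear"
    norm <- percentile_normalize(mm, q = q, log2_transform = FALSE)
    expect_equal(percentile_oracle(norm$sham_1, q), 1, tolerance = 1e-12)
  }
})

test_that("normalization is idempotent on the linear scale", {
  m <- tiny_expression_matrix()
  once <- percentile_normalize(m, log2_transform = FALSE)
  twice <- percentile_normalize(once, log2_transform = FALSE)
  expect_equal(tibble::as_tibble(once), tibble::as_tibble(twice),
               tolerance = 1e-12)
})

test_that("non-positive intensities are refused with probes named", {
  m <- tiny_expression_matrix()
  m$sham_1[2] <- 0
  expect_error(percentile_normalize(m), "g1_p2",
               class = "regenexpr_intensity_error")
  expect_error(percentile_normalize(percentile_normalize(tiny_expression_matrix())),
               class = "regenexpr_scale_error")
})

test_that("replicate probes collapse to per-array medians", {
  m <- percentile_normalize(tiny_expression_matrix())
  g <- collapse_replicate_probes(m)
  expect_equal(nrow(g), 3)
  expect_setequal(g$gene_id, c("g1", "g2", "g3"))

  # a 9-replicate group of identical rows collapses to the common row
  m9 <- tibble::tibble(probe_id = sprintf("p%d", 1:9),
                       gene_id = "g", replicate_group = "g",
                       sham_1 = rep(3, 9), crush_1 = rep(5, 9))
  attr(m9, "scale") <- "log2"
  g9 <- collapse_replicate_probes(m9)
  expect_equal(c(g9$sham_1, g9$crush_1), c(3, 5))

  # median is robust to a single outlier
  m3 <- tibble::tibble(probe_id = c("a", "b", "c"), gene_id = "g",
                       replicate_group = "g",
                       sham_1 = c(1, 2, 100), crush_1 = c(0, 0, 0))
  attr(m3, "scale") <- "log2"
  expect_equal(collapse_replicate_probes(m3)$sham_1, 2)

  # random groups against a brute-force per-cell median oracle
  set.seed(52)
  mm <- tibble::tibble(
    probe_id = sprintf("p%d", 1:30),
    gene_id = sample(sprintf("g%d", 1:7), 30, replace = TRUE),
    sham_1 = rnorm(30), crush_1 = rnorm(30))
  mm$replicate_group <- mm$gene_id
  attr(mm, "scale") <- "log2"
  got <- collapse_replicate_probes(mm)
  for (g in unique(mm$replicate_group)) {
    rows <- mm[mm$replicate_group == g, ]
    expect_equal(got$sham_1[got$gene_id == g], median_oracle(rows$sham_1))
    expect_equal(got$crush_1[got$gene_id == g], median_oracle(rows$crush_1))
  }

  mm$replicate_group[3] <- NA
  expect_error(collapse_replicate_probes(mm),
               class = "regenexpr_schema_error")
})

test_that("gene t-test matches the reference Student t-test", {
  expect_equal(gene_ttest(c(1, 2, 3), c(1, 2, 3)),
               tibble::tibble(t = 0, df = 4, p = 1, degenerate = FALSE))
  # near-zero variance with clear separation
  tt <- gene_ttest(c(0, 0, 0, 0), c(1, 1, 1, 1.0001))
  expect_lt(tt$p, 1e-6)
  # exact zero pooled variance with separation: flagged degenerate
  tt <- gene_ttest(c(0, 0), c(1, 1))
  expect_true(tt$degenerate)
  expect_equal(tt$p, 0)

  set.seed(53)
  for (i in 1:10) {
    x <- rnorm(4); y <- rnorm(4, 0.5)
    got <- gene_ttest(x, y)
    ref <- stats::t.test(y, x, var.equal = TRUE)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(gene_ttest(1, c(1, 2)), class = "regenexpr_insufficient_data")
})

test_that("the published count breakdown arithmetic is reproduced", {
  s <- de_summary_from_counts(n_tested = 10333, n_significant = 348,
                              n_up = 42, n_down = 25)
  expect_equal(s$n_fc, 67)
  expect_equal(round_half_up(s$pct_fc_of_significant, 1), 19.3)
  expect_equal(round_half_up(s$pct_up_of_significant, 0), 12)
  expect_equal(round_half_up(s$pct_down_of_significant, 0), 7)
  expect_equal(round_half_up(s$pct_lt_fc_of_significant, 1), 80.7)
  expect_error(de_summary_from_counts(100, 200, 1, 1),
               class = "regenexpr_param_error")
})

test_that("run_de recovers spiked genes and keeps count invariants", {
  spike <- stats::setNames(rep(c(2, -2), 10), sprintf("gene_%05d", 1:20))
  for (seed in c(101, 102, 103)) {
    s <- simulate_microarray(array_sim_params(
      n_unique_probes = 220, n_duplicated = 40, n_technical = 2,
      true_log2_fc = spike, biological_sd = 0.25, seed = seed))
    de <- run_de(s$matrix)
    hits <- tibble::as_tibble(de) |>
      dplyr::filter(passes_p, passes_fc) |>
      dplyr::pull(gene_id)
    expect_gte(length(intersect(hits, names(spike))), 18)
    s2 <- de_summary(de)
    expect_lte(s2$n_fc, s2$n_significant)
    expect_lte(s2$n_significant, s2$n_tested)
    expect_equal(s2$n_fc, s2$n_up + s2$n_down)
    # per-gene consistency of filters and signs
    d <- tibble::as_tibble(de)
    expect_equal(d$passes_fc, abs(d$log2_fc) >= 1)
    expect_equal(sign(d$fold_change_signed), sign(d$log2_fc))
    expect_true(all(d$p_value >= 0 & d$p_value <= 1))
  }
})

test_that("run_de is invariant to probe and array order", {
  s <- simulate_microarray(array_sim_params(
    n_unique_probes = 80, n_duplicated = 20, n_technical = 2,
    true_log2_fc = c(gene_00001 = 1.5), seed = 61))
  m <- s$matrix
  set.seed(62)
  shuffled <- m[sample(nrow(m)), c("probe_id", "gene_id", "replicate_group",
                                   sample(setdiff(names(m), c("probe_id",
                                          "gene_id", "replicate_group"))))]
  attr(shuffled, "scale") <- "linear"
  r1 <- tibble::as_tibble(run_de(m)) |> dplyr::arrange(gene_id)
  r2 <- tibble::as_tibble(run_de(shuffled)) |> dplyr::arrange(gene_id)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("run_de refuses designs that cannot be tested", {
  m <- tiny_expression_matrix()
  expect_error(run_de(m[c("probe_id", "gene_id", "replicate_group",
                          "sham_1", "sham_2")]),
               class = "regenexpr_design_error")
  expect_error(run_de(m[c("probe_id", "gene_id", "replicate_group",
                          "sham_1", "crush_1", "crush_2")]),
               class = "regenexpr_design_error")
  expect_error(run_de(m, alpha = 1.5), class = "regenexpr_param_error")
})

test_that("hierarchical clustering matches a brute-force UPGMA oracle", {
  set.seed(71)
  m <- matrix(rnorm(10 * 6), 10, 6,
              dimnames = list(sprintf("g%d", 1:10), NULL))
  hc <- hierarchical_cluster(m)
  expect_setequal(hc$order, 1:10)
  expect_true(all(diff(hc$height) >= -1e-12))

  d <- 1 - stats::cor(t(m))
  steps <- upgma_oracle(stats::as.dist(d))
  sets <- hclust_merge_sets(hc$hclust)
  for (k in seq_along(steps)) {
    expect_equal(sets[[k]], steps[[k]]$members)
    expect_equal(hc$height[k], steps[[k]]$height, tolerance = 1e-10)
  }
})

test_that("clustering handles identical, anti-correlated and flat genes", {
  base <- c(1, 2, 3, 4)
  m <- rbind(a = base, b = base, c = rev(base))
  hc <- hierarchical_cluster(m)
  sets <- hclust_merge_sets(hc$hclust)
  expect_equal(sets[[1]], c(1, 2))       # identical pair merges first
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  expect_gt(hc$height[2], 1.5)           # anti-correlated joins at ~2

  flat <- rbind(a = base, b = rep(1, 4), c = base + 1)
  expect_message(hcf <- hierarchical_cluster(flat), "zero-variance")
  expect_equal(hclust_merge_sets(hcf$hclust)[[1]], c(1, 3))

  expect_error(hierarchical_cluster(m[1, , drop = FALSE]),
               class = "regenexpr_insufficient_data")
})

test_that("cluster trees serialize to valid Newick", {
  set.seed(72)
  m <- matrix(rnorm(5 * 6), 5, 6, dimnames = list(letters[1:5], NULL))
  hc <- hierarchical_cluster(m)
  txt <- cluster_newick(hc)
  phy <- ape::read.tree(text = txt)
  expect_setequal(phy$tip.label, letters[1:5])
  path <- withr::local_tempfile(fileext = ".nwk")
  cluster_newick(hc, path)
  expect_identical(readLines(path), txt)
})
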