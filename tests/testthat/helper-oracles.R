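# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and lm/quantile/hclust) so that agreement is evidence of
# correctness, not shared bugs.

# OLS via explicit normal equations.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# Type-7 percentile by direct order-statistic interpolation.
percentile_oracle <- function(v, q) {
  v <- sort(v)
  h <- (length(v) - 1) * q / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# Median without stats::median.
median_oracle <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
}

# One-way ANOVA by explicit sums of squares.
anova_oracle <- function(groups) {
  all <- unlist(groups)
  grand <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1
  dfw <- length(all) - length(groups)
  F <- (ssb / dfb) / (ssw / dfw)
  list(F = F, df_between = dfb, df_within = dfw,
       p = stats::pf(F, dfb, dfw, lower.tail = FALSE),
       ms_between = ssb / dfb, ms_within = ssw / dfw)
}

# Holm-Sidak by literal step-down enumeration.
holm_sidak_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    cand <- 1 - (1 - p[ord[i]])^(m - i + 1)
    running <- max(running, cand)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

# UPGMA (average linkage on the original dissimilarities) by naive O(n^3)
# agglomeration. Returns merge heights and the member sets merged at each
# step, for comparison with an hclust tree.
upgma_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  active <- seq_len(n)
  steps <- list()
  # cluster-to-cluster distance: mean over all cross pairs of original d
  cdist <- function(a, b) mean(d[clusters[[a]], clusters[[b]]])
  while (length(active) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(active)) for (j in seq_len(i - 1)) {
      dd <- cdist(active[i], active[j])
      if (dd < best_d) { best_d <- dd; best <- c(active[j], active[i]) }
    }
    new_id <- length(clusters) + 1
    clusters[[new_id]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    steps[[length(steps) + 1]] <- list(height = best_d,
                                       members = clusters[[new_id]])
    active <- c(setdiff(active, best), new_id)
  }
  steps
}

# Member sets at each merge of an hclust tree, in merge order.
hclust_merge_sets <- function(hc) {
  sets <- list()
  for (k in seq_len(nrow(hc$merge))) {
    members <- function(id) {
      if (id < 0) return(-id)
      sets[[id]]
    }
    sets[[k]] <- sort(c(members(hc$merge[k, 1]), members(hc$merge[k, 2])))
  }
  sets
}

# Shared small fixture: a probe-level expression tibble built by hand
# (3 genes, one duplicated probe pair, 2+2 arrays, known values).
tiny_expression_matrix <- function() {
  m <- tibble::tibble(
    probe_id = c("g1_p1", "g1_p2", "g2_p1", "g3_p1"),
    gene_id = c("g1", "g1", "g2", "g3"),
    replicate_group = c("g1", "g1", "g2", "g3"),
    sham_1 = c(8, 8, 16, 4),
    sham_2 = c(16, 16, 32, 8),
    crush_1 = c(8, 8, 16, 4),
    crush_2 = c(8, 8, 16, 4)
  )
  attr(m, "scale") <- "linear"
  m
}
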