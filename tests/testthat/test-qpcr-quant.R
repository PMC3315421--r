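test_that("efficiency follows m = -1/log10(E)", {
  expect_equal(efficiency_from_slope(-1 / log10(2)), 2, tolerance = 1e-12)
  expect_equal(efficiency_from_slope(-3.3219), 2, tolerance = 1e-4)
  expect_equal(efficiency_from_slope(-3.52), 1.9235, tolerance = 1e-4)
  # very steep slopes approach efficiency 1 from above
  expect_equal(efficiency_from_slope(-1000), 1.0023, tolerance = 1e-4)
  expect_gt(efficiency_from_slope(-1000), 1)
  expect_error(efficiency_from_slope(3.3), class = "regenexpr_domain_error")
  expect_error(efficiency_from_slope(0), class = "regenexpr_domain_error")
})

test_that("standard-curve fit matches hand points and the OLS oracle", {
  d <- data.frame(x = c(0, 1, 2), ct = c(30, 26.678, 23.356))
  fit <- fit_standard_curve(d, x, ct, gene_name = "CEBP")
  expect_equal(fit$slope_m, -3.322, tolerance = 1e-3)
  expect_equal(fit$efficiency, 2, tolerance = 1e-3)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_false(fit$efficiency_flag)

  set.seed(21)
  for (i in 1:5) {
    x <- rep(0:-3, each = 2)
    y <- 28 - 3.4 * x + rnorm(8, 0, 0.3)
    fit <- fit_standard_curve(data.frame(x = x, y = y), x, y)
    o <- ols_oracle(x, y)
    expect_equal(fit$slope_m, unname(o["slope"]), tolerance = 1e-9)
    expect_equal(fit$intercept, unname(o["intercept"]), tolerance = 1e-9)
  }

  expect_error(fit_standard_curve(data.frame(x = c(0, 0, 1),
                                             ct = c(30, 30, 27)), x, ct),
               class = "regenexpr_insufficient_data")
  # rising Ct with template amount: efficiency undefined
  expect_error(fit_standard_curve(data.frame(x = 0:2, ct = c(20, 24, 28)),
                                  x, ct),
               class = "regenexpr_degenerate_curve")
})

test_that("Ct-Ct regression recovers the efficiency-ratio slope", {
  pair_up <- function(sim) {
    tidyr::pivot_wider(sim$ct, id_cols = c("sample_id", "condition", "dilution"),
                       names_from = "gene_role", values_from = "ct")
  }
  w <- pair_up(simulate_qpcr(qpcr_sim_params(
    R_by_condition = c(a = 5), E_target = 2, E_control = 2,
    ct_noise_sd = 0, seed = 4)))
  expect_equal(fit_ctct(w, control, target)$slope_m, 1, tolerance = 1e-10)

  w <- pair_up(simulate_qpcr(qpcr_sim_params(
    R_by_condition = c(a = 5), E_target = 1.9, E_control = 2,
    ct_noise_sd = 0, n_samples_per_condition = 10, seed = 5)))
  expect_equal(fit_ctct(w, control, target)$slope_m, log(2) / log(1.9),
               tolerance = 1e-9)

  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(8, 25, 2); y <- 1.1 * x - 2 + rnorm(8, 0, 0.3)
    fit <- fit_ctct(data.frame(cc = x, ct = y), cc, ct)
    o <- ols_oracle(x, y)
    expect_equal(fit$slope_m, unname(o["slope"]), tolerance = 1e-9)
    expect_equal(fit$y_intercept, unname(o["intercept"]), tolerance = 1e-9)
  }

  same <- data.frame(cc = rep(25, 4), ct = c(24, 25, 26, 27))
  expect_error(fit_ctct(same, cc, ct), "unidentifiable",
               class = "regenexpr_degenerate_fit")
})

test_that("intercepts map to ratios by R = E^(-Yint)", {
  expect_equal(ratio_from_intercept(0, 2), 1)
  expect_equal(ratio_from_intercept(0, 1.8), 1)
  expect_equal(ratio_from_intercept(-log10(10) / log10(2), 2), 10,
               tolerance = 1e-10)
  expect_equal(ratio_from_intercept(log10(10) / log10(2), 2), 0.1,
               tolerance = 1e-10)
  # reciprocal symmetry R(-y) = 1/R(y)
  for (y in c(0.3, 1.7, 4)) {
    expect_equal(ratio_from_intercept(-y, 1.9),
                 1 / ratio_from_intercept(y, 1.9), tolerance = 1e-12)
  }
  expect_error(ratio_from_intercept(1, 0.9), class = "regenexpr_domain_error")
})

test_that("full pipeline inverts the generator on a (R, E) grid", {
  for (R in c(0.1, 1, 2, 10)) {
    for (E in c(1.8, 1.9, 2.0)) {
      sim <- simulate_qpcr(qpcr_sim_params(
        R_by_condition = c(x = R), E_target = E, E_control = E,
        ct_noise_sd = 0, seed = 1000 + round(100 * R + E * 10)))
      w <- tidyr::pivot_wider(sim$ct, id_cols = c("sample_id", "dilution"),
                              names_from = "gene_role", values_from = "ct")
      fit <- fit_ctct(w, control, target)
      expect_equal(ratio_from_intercept(fit$y_intercept, E), R,
                   tolerance = 1e-9)
    }
  }
})

test_that("condition fold change behaves under identity, shift and swap", {
  sim <- simulate_qpcr(qpcr_sim_params(
    R_by_condition = c(sham = 1, crush = 7.36),
    ct_noise_sd = 0, n_samples_per_condition = 5, seed = 8))
  w <- tidyr::pivot_wider(sim$ct, id_cols = c("sample_id", "condition", "dilution"),
                          names_from = "gene_role", values_from = "ct")
  f_sham <- fit_ctct(dplyr::filter(w, condition == "sham"), control, target,
                     condition = "sham")
  f_crush <- fit_ctct(dplyr::filter(w, condition == "crush"), control, target,
                      condition = "crush")
  E <- 1.923
  expect_equal(condition_fold_change(f_crush, f_sham, E), 7.36,
               tolerance = 1e-9)
  # identity and reciprocal swap
  expect_equal(condition_fold_change(f_sham, f_sham, E), 1)
  expect_equal(condition_fold_change(f_sham, f_crush, E),
               1 / condition_fold_change(f_crush, f_sham, E),
               tolerance = 1e-12)
  # a one-cycle intercept drop at E = 2 doubles expression
  f2 <- f_crush; f2$y_intercept <- f_sham$y_intercept - 1
  expect_equal(condition_fold_change(f2, f_sham, 2), 2, tolerance = 1e-12)
  # fold change decreases monotonically in the crush intercept
  folds <- vapply(c(-1, 0, 1, 2), function(shift) {
    f <- f_crush; f$y_intercept <- f_crush$y_intercept + shift
    condition_fold_change(f, f_sham, E)
  }, 0)
  expect_true(all(diff(folds) < 0))
  # time-point mismatch is refused
  f3 <- f_crush; f3$time_hr <- 3; f4 <- f_sham; f4$time_hr <- 1
  expect_error(condition_fold_change(f3, f4, E),
               class = "regenexpr_pairing_error")
})

test_that("timecourse quantification recovers noise-free truth exactly", {
  truth <- c("1" = 7.36, "3" = 2.35, "5" = 1.98)
  sim <- simulate_qpcr_timecourse(truth, qpcr_sim_params(
    ct_noise_sd = 0, n_groups = 5, seed = 10))
  tc <- suppressMessages(quantify_timecourse(sim$ct, efficiency_target = 1.923))
  expect_equal(tc$fold_change, unname(truth), tolerance = 1e-9)
  expect_equal(tc$sem, rep(0, 3), tolerance = 1e-9)
  expect_equal(tc$n, rep(5L, 3))
  qc <- ctct_qc(tc)
  expect_false(any(qc$flagged))
  expect_equal(qc$slope, rep(1, nrow(qc)), tolerance = 1e-9)
})

test_that("single replicate group reports n = 1 with absent SEM", {
  sim <- simulate_qpcr(qpcr_sim_params(
    R_by_condition = c(sham = 1, crush = 2), ct_noise_sd = 0, seed = 12))
  tc <- suppressMessages(quantify_timecourse(sim$ct, efficiency_target = 1.923))
  expect_equal(tc$n, 1L)
  expect_true(is.na(tc$sem))
  expect_equal(tc$fold_change, 2, tolerance = 1e-9)
})

test_that("a missing condition at a time point is reported as a gap", {
  sim <- simulate_qpcr_timecourse(c("1" = 2, "3" = 2),
                                  qpcr_sim_params(ct_noise_sd = 0, seed = 13))
  broken <- dplyr::filter(sim$ct, !(time_hr == 3 & condition == "crush"))
  expect_error(quantify_timecourse(broken, efficiency_target = 1.9),
               "3", class = "regenexpr_pairing_error")
})

test_that("equal-efficiency Ct-Ct estimate equals the 2^-ddCt estimate", {
  ddct_estimate <- function(w) {
    d <- w |>
      dplyr::mutate(dct = target - control) |>
      dplyr::group_by(condition) |>
      dplyr::summarise(m = mean(dct), .groups = "drop")
    2^-(d$m[d$condition == "crush"] - d$m[d$condition == "sham"])
  }
  ctct_estimate <- function(w) {
    fs <- fit_ctct(dplyr::filter(w, condition == "sham"), control, target)
    fc <- fit_ctct(dplyr::filter(w, condition == "crush"), control, target)
    2^(fs$y_intercept - fc$y_intercept)
  }
  make <- function(noise, seed) {
    sim <- simulate_qpcr(qpcr_sim_params(
      R_by_condition = c(sham = 1, crush = 2.35), E_target = 2, E_control = 2,
      ct_noise_sd = noise, seed = seed))
    tidyr::pivot_wider(sim$ct, id_cols = c("sample_id", "condition", "dilution"),
                       names_from = "gene_role", values_from = "ct")
  }
  # exact agreement on noise-free data
  w <- make(0, 17)
  expect_equal(ctct_estimate(w), ddct_estimate(w), tolerance = 1e-9)
  expect_equal(ctct_estimate(w), 2.35, tolerance = 1e-9)
  # on noisy data the two estimators agree in expectation (paired MC check)
  set.seed(18)
  diffs <- vapply(1:500, function(i) {
    w <- make(0.3, NULL)
    ctct_estimate(w) - ddct_estimate(w)
  }, 0)
  expect_lt(abs(mean(diffs)), 3 * stats::sd(diffs) / sqrt(length(diffs)) + 0.02)
})
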