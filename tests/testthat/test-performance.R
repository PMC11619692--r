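test_that("required simulation counts reproduce the protocol's planning values", {
  expect_equal(required_simulations(0.8, 0.05), 983L)
  expect_equal(required_simulations(0.5, 0.05), 1537L)
  # monotone in the binomial variance p(1-p)
  expect_lt(required_simulations(0.05, 0.05), required_simulations(0.2, 0.05))
  expect_lt(required_simulations(0.001, 0.05), 10L)
  expect_error(required_simulations(0, 0.05), "p")
  expect_error(required_simulations(0.5, 0), "L")
})

test_that("Clopper-Pearson intervals are exact Beta-quantile intervals", {
  ci0 <- clopper_pearson(0, 1000)
  expect_equal(unname(ci0), c(0, stats::qbeta(0.975, 1, 1000)))
  expect_equal(round(100 * ci0[["upper"]], 1), 0.4)
  ci1 <- clopper_pearson(1000, 1000)
  expect_equal(round(100 * ci1[["lower"]], 1), 99.6)
  expect_equal(ci1[["upper"]], 1)
  cih <- clopper_pearson(500, 1000)
  expect_equal(cih[["lower"]], 1 - cih[["upper"]], tolerance = 1e-10)
  expect_error(clopper_pearson(5, 4), "successes")
})

test_that("MCSE intervals behave like mean +/- z * sd / sqrt(n)", {
  const <- mc_interval_mean(rep(0.3, 10))
  expect_equal(const$estimate, 0.3)
  expect_equal(const$lower, 0.3)
  expect_equal(const$upper, 0.3)
  x <- rep(c(0, 1), 50)
  mi <- mc_interval_mean(x)
  expect_equal(mi$mcse, stats::sd(x) / 10)
  expect_equal(mi$upper - mi$lower, 2 * stats::qnorm(0.975) * stats::sd(x) / 10)
  # width shrinks as 1 / sqrt(n)
  mi4 <- mc_interval_mean(rep(c(0, 1), 200))
  expect_equal((mi$upper - mi$lower) / (mi4$upper - mi4$lower), 2, tolerance = 0.01)
  expect_error(mc_interval_mean(1), "at least 2")
})

# a miniature replicate table covering the column contract of run_study()
fake_replicates <- function(n, conv = rep(TRUE, n)) {
  pars <- c("pi", paste0("Se", 1:4), paste0("Sp", 1:4))
  pairs <- c("T1xT2", "T1xT3", "T1xT4", "T2xT3", "T2xT4", "T3xT4")
  df <- data.frame(label = "HHHH-HHHH", rep = seq_len(n), seed = seq_len(n),
                   converged = conv, residuals_defined = TRUE,
                   overall_chi2 = 1, overall_g2 = 1,
                   overall_chi2_flag = FALSE, overall_g2_flag = FALSE)
  for (pr in pairs) {
    df[[paste0("resid_median_", pr)]] <- 0
    df[[paste0("resid_flag_", pr)]] <- pr == "T1xT2"
    df[[paste0("pw_chi2_flag_", pr)]] <- FALSE
    df[[paste0("pw_g2_flag_", pr)]] <- FALSE
  }
  for (p in pars) {
    df[[paste0("est_", p)]] <- 0.9
    df[[paste0("cri_low_", p)]] <- 0.85
    df[[paste0("cri_high_", p)]] <- 0.95
  }
  df$est_pi <- 0.52; df$cri_low_pi <- 0.45; df$cri_high_pi <- 0.6
  df
}

test_that("scenario aggregation computes detection, bias and coverage correctly", {
  truth <- scenario(0.5, rep(0.9, 4), rep(0.9, 4), omega = 0.5, n_obs = 2000)
  reps <- fake_replicates(40)
  perf <- aggregate_scenario(reps, truth)
  expect_equal(perf$counts$n_converged, 40)
  # residual plot overall = any pairwise flag = always (T1xT2 flag set)
  ov <- perf$detect_overall
  expect_equal(ov$rate[ov$tool == "residual_plot"], 100)
  expect_equal(ov$rate[ov$tool == "overall_chi2"], 0)
  pw <- perf$detect_pairwise
  expect_equal(pw$rate[pw$tool == "residual_plot" & pw$pair == "T1xT2"], 100)
  expect_equal(pw$rate[pw$tool == "residual_plot" & pw$pair == "T3xT4"], 0)
  # all CrIs contain the truth here
  expect_true(all(perf$coverage$coverage == 100))
  # bias of pi: 0.52 - 0.5
  expect_equal(perf$bias$mean_bias[perf$bias$parameter == "pi"], 0.02)
  expect_true(all(perf$detect_overall$lower <= perf$detect_overall$rate &
                    perf$detect_overall$rate <= perf$detect_overall$upper))
})

test_that("the detection denominator is converged replicates, never all replicates", {
  truth <- scenario(0.5, rep(0.9, 4), rep(0.9, 4), omega = 0.5, n_obs = 2000)
  conv <- rep(c(TRUE, FALSE), c(30, 10))
  perf <- aggregate_scenario(fake_replicates(40, conv), truth)
  expect_equal(perf$counts$n_sim, 40)
  expect_equal(perf$counts$n_converged, 30)
  expect_equal(perf$counts$n_excluded, 10)
  expect_true(all(perf$detect_overall$n == 30))
  none <- aggregate_scenario(fake_replicates(5, rep(FALSE, 5)), truth)
  expect_true(none$no_estimate)
  expect_null(none$detect_overall)
})

test_that("cross-scenario pooling equals replicate-weighted recomputation", {
  truth1 <- scenario(0.5, rep(0.9, 4), rep(0.9, 4), omega = 0.5, n_obs = 2000)
  reps1 <- fake_replicates(30)
  reps2 <- fake_replicates(20)
  reps2$label <- "LLHH-LLHH"
  reps2$resid_flag_T1xT2 <- rep(c(TRUE, FALSE), 10)
  truth_table <- rbind(grid_as_data_frame(truth1),
                       grid_as_data_frame(scenario(0.5, c(0.6, 0.6, 0.9, 0.9),
                                                   c(0.6, 0.6, 0.9, 0.9),
                                                   omega = 0.5, n_obs = 2000)))
  pooled <- aggregate_across_scenarios(rbind(reps1, reps2), truth_table, "all")
  pw <- pooled$all$detect_pairwise
  rate <- pw$rate[pw$tool == "residual_plot" & pw$pair == "T1xT2"]
  expect_equal(rate, 100 * (30 + 10) / 50)
  expect_true(rate >= min(100, 50) && rate <= max(100, 50))
  # single-scenario group equals that scenario's own aggregation
  solo <- aggregate_across_scenarios(reps1, truth_table, "all")
  perf1 <- aggregate_scenario(reps1, truth1)
  expect_equal(solo$all$detect_overall$rate, perf1$detect_overall$rate)
})
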