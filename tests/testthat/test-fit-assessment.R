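counts_from_table <- function(n11, n10, n01, n00) {
  # place a 2x2 table for tests (1, 2) in the 16-cell layout with tests 3, 4
  # all negative
  counts <- integer(16)
  counts[8 * 1 + 4 * 1 + 0 + 0 + 1] <- n11
  counts[8 * 1 + 0 + 0 + 0 + 1] <- n10
  counts[0 + 4 * 1 + 0 + 0 + 1] <- n01
  counts[1] <- n00
  pattern_counts(counts)
}

test_that("observed marginal correlation is the phi coefficient of the 2x2 table", {
  expect_equal(observed_marginal_correlation(counts_from_table(50, 0, 0, 50), c(1, 2)), 1)
  # exact product table: independence
  expect_equal(observed_marginal_correlation(counts_from_table(25, 25, 25, 25), c(1, 2)), 0)
  expect_equal(observed_marginal_correlation(counts_from_table(40, 10, 10, 40), c(1, 2)), 0.6)
  # degenerate margin: undefined, not silently propagated
  expect_warning(
    r <- observed_marginal_correlation(counts_from_table(50, 50, 0, 0), c(1, 2)),
    "degenerate")
  expect_true(is.na(r))
})

test_that("fitted marginal correlation matches enumeration and its limits", {
  # single class (pi near the boundary) implies independence
  expect_equal(fitted_marginal_correlation(1e-12, 0.9, 0.9, 0.9, 0.9), 0,
               tolerance = 1e-9)
  # an uninformative test (Se = 1 - Sp) is independent of everything
  expect_equal(fitted_marginal_correlation(0.4, 0.3, 0.9, 0.7, 0.9), 0,
               tolerance = 1e-12)
  # general case against the brute-force 2x2 phi of the exact CInd table
  p <- oracle_pattern_probs(0.5, rep(0.9, 4), rep(0.9, 4))
  tm <- pattern_matrix()
  p11 <- sum(p[tm[, 1] == 1 & tm[, 2] == 1])
  p1 <- sum(p[tm[, 1] == 1]); p2 <- sum(p[tm[, 2] == 1])
  phi <- (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  expect_equal(fitted_marginal_correlation(0.5, 0.9, 0.9, 0.9, 0.9), phi,
               tolerance = 1e-14)
  expect_gt(phi, 0)
})

test_that("goodness-of-fit statistics match hand-computed toy values", {
  s <- gof_statistics(c(10, 20), c(15, 15))
  expect_equal(s$chi2, 10 / 3)
  expect_equal(s$g2, 2 * (10 * log(10 / 15) + 20 * log(20 / 15)))
  exact <- gof_statistics(c(10, 20, 30), c(10, 20, 30))
  expect_equal(exact$chi2, 0)
  expect_equal(exact$g2, 0)
  # zero observed cells use the 0 log 0 = 0 convention
  s0 <- gof_statistics(c(0, 30), c(15, 15))
  expect_equal(s0$g2, 2 * 30 * log(2))
  expect_error(gof_statistics(c(1, 2), c(3, 0)), "cell")
  expect_error(gof_statistics(c(10, 20), c(100, 200)), "sum")
})

test_that("chi2 and G2 are nonnegative, zero only at equality, and agree near it", {
  e <- c(40, 30, 20, 10)
  for (eps in c(2, 1, 0.5, 0.1)) {
    o <- e + c(eps, -eps, eps, -eps)
    s <- gof_statistics(o, e)
    expect_gt(s$chi2, 0)
    expect_gt(s$g2, 0)
    if (eps <= 0.5) expect_equal(s$chi2 / s$g2, 1, tolerance = 0.05)
  }
})

test_that("expected frequencies follow the model and sum to n", {
  unif <- stats::setNames(rep(0.5, 9), c("pi", paste0("Se", 1:4), paste0("Sp", 1:4)))
  e <- expected_frequencies(unif, 1600)
  expect_equal(e, rep(100, 16))
  params <- stats::setNames(c(0.5, rep(0.9, 8)), names(unif))
  e2 <- expected_frequencies(params, 2000)
  expect_equal(sum(e2), 2000)
  expect_equal(e2[16], 2000 * (0.5 * 0.9^4 + 0.5 * 0.1^4)) # all-positive pattern
})

test_that("pairwise collapse is consistent with the 16-cell representation", {
  sc <- scenario(0.4, c(0.9, 0.9, 0.6, 0.9), c(0.6, 0.9, 0.9, 0.6),
                 omega = 0.6, n_obs = 3000)
  d <- simulate_dataset(sc, seed = 31)
  params <- stats::setNames(c(0.4, sc$sensitivities, sc$specificities),
                            c("pi", paste0("Se", 1:4), paste0("Sp", 1:4)))
  e <- expected_frequencies(params, d$n_obs)
  for (pair in list(c(1, 2), c(2, 4), c(3, 4))) {
    o2 <- lcmgof:::collapse_pair(d$counts, pair)
    e2 <- lcmgof:::collapse_pair(e, pair)
    expect_equal(sum(o2), d$n_obs)
    expect_equal(sum(e2), d$n_obs, tolerance = 1e-9)
    # agreement from the collapsed table equals agreement from 16 cells
    expect_equal((o2[1] + o2[4]) / d$n_obs,
                 unname(agreement_probabilities(d)[sprintf("T%dxT%d", pair[1], pair[2])]))
  }
})

test_that("pairwise and overall flags fire exactly at the chi-squared critical values", {
  expect_equal(stats::qchisq(0.95, 1), 3.841459, tolerance = 1e-6)
  expect_equal(stats::qchisq(0.95, 6), 12.59159, tolerance = 1e-6)
  # build 2-cell statistics straddling the df = 1 threshold via gof_statistics
  s_hi <- gof_statistics(c(69, 31), c(50, 50))  # chi2 = 14.44
  expect_gt(s_hi$chi2, stats::qchisq(0.95, 1))
  s_lo <- gof_statistics(c(59, 41), c(50, 50))  # chi2 = 3.24
  expect_lt(s_lo$chi2, stats::qchisq(0.95, 1))
})

test_that("residuals vanish when the posterior sits at the generating parameters", {
  # counts equal to the exact expected frequencies of a CInd model, assessed
  # with draws degenerate at the truth
  params <- stats::setNames(c(0.5, rep(c(0.9, 0.9, 0.6, 0.6), 2)),
                            c("pi", paste0("Se", 1:4), paste0("Sp", 1:4)))
  # n chosen so every expected frequency is an integer (cell probabilities
  # are rationals with denominator 2e4 for these parameter values)
  probs <- cind_pattern_probs(params[1], params[2:5], params[6:9])
  counts <- pattern_counts(round(20000 * probs))
  expect_equal(counts$counts, 20000 * probs, tolerance = 1e-9)
  fake_fit <- structure(list(chains = list(
    matrix(rep(params, each = 50), 50, dimnames = list(NULL, names(params))))),
    class = "lcm_posterior"
  )
  res <- residual_correlations(counts, fake_fit)
  expect_true(all(abs(res$median) < 1e-12))
  expect_true(all(res$cri_high - res$cri_low < 1e-12))
  expect_true(all(res$cri_low <= res$cri_high))
})

test_that("assess_fit assembles a coherent assessment", {
  sc <- scenario(0.5, c(0.6, 0.6, 0.9, 0.9), c(0.6, 0.6, 0.9, 0.9),
                 omega = 0.5, n_obs = 2000)
  d <- simulate_dataset(sc, seed = 17)
  fit <- gibbs_fit(d, quick_mcmc(), seed = 17)
  g <- assess_fit(d, fit)
  expect_s3_class(g, "lcm_gof")
  expect_gte(g$overall$chi2, 0)
  expect_gte(g$overall$g2, 0)
  expect_identical(g$overall$df, 6L)
  expect_equal(nrow(g$residuals), 6)
  expect_true(all(g$agreement$observed >= 0 & g$agreement$observed <= 1))
  expect_true(all(g$agreement$fitted >= 0 & g$agreement$fitted <= 1))
  expect_identical(g$residuals$flag, g$residuals$cri_low > 0 | g$residuals$cri_high < 0)
  p <- plot_residuals(g)
  expect_s3_class(p, "ggplot")
})
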