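# Goodness-of-fit tooling for one fitted data set: residual correlations
# with credible intervals, overall and pairwise chi-squared / G2 statistics
# (evaluated at the posterior medians), and pairwise agreement probabilities.

# collapse 16 pattern counts (or frequencies) to the 2x2 table of (T_i, T_j)
# outcomes, returned in the order (1,1), (1,0), (0,1), (0,0)
collapse_pair <- function(cells, pair) {
  tm <- pattern_matrix()
  ti <- tm[, pair[1]]; tj <- tm[, pair[2]]
  c(sum(cells[ti == 1 & tj == 1]), sum(cells[ti == 1 & tj == 0]),
    sum(cells[ti == 0 & tj == 1]), sum(cells[ti == 0 & tj == 0]))
}

#' Observed marginal correlation of a test pair
#'
#' Pearson (phi) correlation of the observed 2x2 table of tests i and j,
#' computed from the marginalized pattern counts:
#' `(P(Ti=1, Tj=1) - P(Ti=1) P(Tj=1)) / sqrt(P(Ti=1)(1-P(Ti=1)) P(Tj=1)(1-P(Tj=1)))`.
#'
#' @param counts A [pattern_counts()] object.
#' @param pair Integer pair `c(i, j)`, `1 <= i < j <= 4`.
#' @return The observed correlation, or `NA_real_` (with a warning) when a
#'   test is all-positive or all-negative so the correlation is undefined.
#' @export
observed_marginal_correlation <- function(counts, pair) {
  stopifnot(inherits(counts, "pattern_counts"), length(pair) == 2L)
  tab <- collapse_pair(counts$counts, pair)
  n <- counts$n_obs
  pi1 <- (tab[1] + tab[2]) / n
  pj1 <- (tab[1] + tab[3]) / n
  if (pi1 %in% c(0, 1) || pj1 %in% c(0, 1)) {
    warning(sprintf("observed correlation undefined for pair (%d,%d): degenerate margin",
                    pair[1], pair[2]))
    return(NA_real_)
  }
  pij <- tab[1] / n
  (pij - pi1 * pj1) / sqrt(pi1 * (1 - pi1) * pj1 * (1 - pj1))
}

#' Fitted marginal correlation under the conditional-independence model
#'
#' Marginal Pearson correlation between tests i and j implied by model
#' parameters: with `P(Ti=1) = pi Se_i + (1-pi)(1-Sp_i)` and
#' `P(Ti=1, Tj=1) = pi Se_i Se_j + (1-pi)(1-Sp_i)(1-Sp_j)`, the same phi
#' formula as the observed correlation. Vectorized over draws.
#'
#' @param prevalence,se_i,se_j,sp_i,sp_j Parameter values (scalars or
#'   equal-length vectors of posterior draws), strictly inside (0, 1).
#' @return Fitted correlation(s).
#' @export
fitted_marginal_correlation <- function(prevalence, se_i, se_j, sp_i, sp_j) {
  pi1 <- prevalence * se_i + (1 - prevalence) * (1 - sp_i)
  pj1 <- prevalence * se_j + (1 - prevalence) * (1 - sp_j)
  pij <- prevalence * se_i * se_j + (1 - prevalence) * (1 - sp_i) * (1 - sp_j)
  (pij - pi1 * pj1) / sqrt(pi1 * (1 - pi1) * pj1 * (1 - pj1))
}

#' Residual correlations with 95% credible intervals
#'
#' For each test pair, the residual correlation is the observed marginal
#' correlation minus the model-fitted one; the fitted correlation is
#' evaluated at every retained posterior draw, giving a posterior
#' distribution for each residual, summarized by its median and equal-tailed
#' 95% credible interval. The flag is `TRUE` when the interval strictly
#' excludes zero.
#'
#' @param counts A [pattern_counts()] object.
#' @param fit An `lcm_posterior` object from [gibbs_fit()].
#' @return A data.frame with one row per pair: `pair`, `observed`, `median`,
#'   `cri_low`, `cri_high`, `flag`, `defined`.
#' @export
residual_correlations <- function(counts, fit) {
  draws <- pooled_draws(fit)
  pairs <- test_pairs()
  out <- lapply(seq_along(pairs), function(p) {
    pr <- pairs[[p]]
    r_obs <- suppressWarnings(observed_marginal_correlation(counts, pr))
    if (is.na(r_obs)) {
      return(data.frame(pair = pair_names()[p], observed = NA_real_,
                        median = NA_real_, cri_low = NA_real_,
                        cri_high = NA_real_, flag = NA, defined = FALSE))
    }
    r_fit <- fitted_marginal_correlation(draws[, "pi"],
                                         draws[, paste0("Se", pr[1])],
                                         draws[, paste0("Se", pr[2])],
                                         draws[, paste0("Sp", pr[1])],
                                         draws[, paste0("Sp", pr[2])])
    rho <- r_obs - r_fit
    q <- stats::quantile(rho, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(pair = pair_names()[p], observed = r_obs, median = q[2],
               cri_low = q[1], cri_high = q[3],
               flag = q[1] > 0 || q[3] < 0, defined = TRUE)
  })
  do.call(rbind, out)
}

#' Expected pattern frequencies under the conditional-independence model
#'
#' @param params Named 9-vector (pi, Se1..Se4, Sp1..Sp4), e.g. posterior
#'   medians from [summarize_posterior()].
#' @param n_obs Total number of subjects.
#' @return Numeric vector of 16 expected frequencies summing to `n_obs`.
#' @export
expected_frequencies <- function(params, n_obs) {
  stopifnot(length(params) == 9L)
  n_obs * cind_pattern_probs(params[1], params[2:5], params[6:9])
}

#' Pearson chi-squared and likelihood-ratio statistics
#'
#' `chi2 = sum (O_k - E_k)^2 / E_k` and `g2 = 2 sum O_k log(O_k / E_k)`,
#' with the `0 * log(0) = 0` convention for empty observed cells.
#'
#' @param observed Nonnegative observed counts.
#' @param expected Positive expected frequencies summing to the observed total.
#' @return A list with elements `chi2` and `g2`.
#' @export
gof_statistics <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  if (any(expected <= sqrt(.Machine$double.eps))) {
    stop(sprintf("expected frequency in cell %d is not positive",
                 which(expected <= sqrt(.Machine$double.eps))[1L]))
  }
  if (abs(sum(observed) - sum(expected)) > 1e-6 * sum(observed)) {
    stop("expected frequencies must sum to the observed total")
  }
  chi2 <- sum((observed - expected)^2 / expected)
  nz <- observed > 0
  g2 <- 2 * sum(observed[nz] * log(observed[nz] / expected[nz]))
  list(chi2 = chi2, g2 = g2)
}

# 95% critical values from the chi-squared quantile function
chi2_crit_df1 <- function() stats::qchisq(0.95, df = 1)
chi2_crit_df6 <- function() stats::qchisq(0.95, df = 6)

#' Overall goodness-of-fit test on the 16 cells
#'
#' Chi-squared and G2 statistics over all 16 pattern cells, referred to the
#' 95% critical value of a chi-squared distribution with
#' `df = 2^4 - 9 - 1 = 6` (9 freely estimated parameters).
#'
#' @param counts A [pattern_counts()] object.
#' @param params Named 9-vector of plug-in parameters (posterior medians).
#' @return List with `chi2`, `g2`, `chi2_flag`, `g2_flag`, `df`.
#' @export
overall_gof <- function(counts, params) {
  e <- expected_frequencies(params, counts$n_obs)
  s <- gof_statistics(counts$counts, e)
  crit <- chi2_crit_df6()
  list(chi2 = s$chi2, g2 = s$g2,
       chi2_flag = s$chi2 > crit, g2_flag = s$g2 > crit, df = 6L)
}

#' Pairwise goodness-of-fit test on a 2x2 agreement table
#'
#' Collapses observed counts and model-expected frequencies to the 2x2 table
#' of (T_i, T_j) outcomes and applies the chi-squared and G2 statistics over
#' its 4 cells, referred to the 95% critical value with df = 1.
#'
#' @inheritParams overall_gof
#' @param pair Integer pair `c(i, j)`.
#' @return List with `chi2`, `g2`, `chi2_flag`, `g2_flag`.
#' @export
pairwise_gof <- function(counts, params, pair) {
  o <- collapse_pair(counts$counts, pair)
  e <- collapse_pair(expected_frequencies(params, counts$n_obs), pair)
  s <- gof_statistics(o, e)
  crit <- chi2_crit_df1()
  list(chi2 = s$chi2, g2 = s$g2,
       chi2_flag = s$chi2 > crit, g2_flag = s$g2 > crit)
}

#' Full goodness-of-fit assessment of one fitted data set
#'
#' Combines the residual correlations (per-draw, with 95% CrIs), the
#' overall and six pairwise chi-squared / G2 statistics evaluated at the
#' posterior medians, and the observed and fitted pairwise agreement
#' probabilities.
#'
#' @param counts A [pattern_counts()] object.
#' @param fit An `lcm_posterior` object for the same counts.
#' @return An object of class `lcm_gof` with components `residuals` (data
#'   frame from [residual_correlations()]), `overall`, `pairwise` (data
#'   frame, one row per pair), `agreement` (observed and fitted), and
#'   `converged` carried over from the fit.
#' @export
assess_fit <- function(counts, fit) {
  if (inherits(counts, "integer") || (is.numeric(counts) && length(counts) == 16L)) {
    counts <- pattern_counts(counts)
  }
  medians <- summarize_posterior(fit)$medians
  res <- residual_correlations(counts, fit)
  ov <- overall_gof(counts, medians)
  pw <- lapply(test_pairs(), function(pr) pairwise_gof(counts, medians, pr))
  pairwise <- data.frame(
    pair = pair_names(),
    chi2 = vapply(pw, `[[`, numeric(1), "chi2"),
    g2 = vapply(pw, `[[`, numeric(1), "g2"),
    chi2_flag = vapply(pw, `[[`, logical(1), "chi2_flag"),
    g2_flag = vapply(pw, `[[`, logical(1), "g2_flag"))
  fitted_probs <- cind_pattern_probs(medians[1], medians[2:5], medians[6:9])
  structure(list(
    residuals = res,
    overall = ov,
    pairwise = pairwise,
    agreement = data.frame(pair = pair_names(),
                           observed = as.numeric(agreement_probabilities(counts)),
                           fitted = as.numeric(agreement_probabilities(fitted_probs))),
    medians = medians,
    converged = fit$converged,
    rhat = fit$rhat, n_eff = fit$n_eff),
    class = "lcm_gof")
}

#' @export
print.lcm_gof <- function(x, ...) {
  cat("Goodness-of-fit assessment (converged:", x$converged, ")\n")
  cat(sprintf("  overall chi2 = %.2f (flag %s), G2 = %.2f (flag %s), df = 6\n",
              x$overall$chi2, x$overall$chi2_flag,
              x$overall$g2, x$overall$g2_flag))
  cat("  residual correlations:\n")
  print(x$residuals, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Residual correlation plot
#'
#' The classic display of lack of fit: posterior-median residual
#' correlations with 95% credible intervals for the six test pairs, around
#' a zero reference line. Intervals excluding zero indicate pairwise misfit.
#'
#' @param assessment An `lcm_gof` object from [assess_fit()], or the data
#'   frame returned by [residual_correlations()].
#' @return A ggplot object.
#' @export
plot_residuals <- function(assessment) {
  res <- if (inherits(assessment, "lcm_gof")) assessment$residuals else assessment
  res$pair <- factor(res$pair, levels = pair_names())
  ggplot2::ggplot(res, ggplot2::aes(x = .data$pair, y = .data$median)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$cri_low,
                                          ymax = .data$cri_high)) +
    ggplot2::labs(x = "Test pair", y = "Residual correlation",
                  title = "Residual correlations with 95% credible intervals") +
    ggplot2::theme_minimal()
}
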