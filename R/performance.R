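# ADEMP performance measures: detection rates, bias and coverage with
# Monte Carlo uncertainty (Clopper-Pearson intervals for proportions,
# MCSE-based intervals for means).

z975 <- function() stats::qnorm(0.975)

#' Required number of simulation replicates
#'
#' Number of replicates needed so that the 95% Monte Carlo confidence
#' interval around an estimated proportion `p` has maximum length `L`:
#' `(z * sqrt(p (1 - p)) / (L / 2))^2`, rounded to the nearest integer.
#'
#' @param p Anticipated proportion, in (0, 1).
#' @param L Maximum interval length, > 0.
#' @return Required number of simulations (integer).
#' @examples
#' required_simulations(0.8, 0.05) # 983
#' @export
required_simulations <- function(p, L) {
  stopifnot(length(p) == 1L, length(L) == 1L)
  if (p <= 0 || p >= 1) stop("p must be strictly inside (0, 1)")
  if (L <= 0) stop("L must be positive")
  as.integer(round((z975() * sqrt(p * (1 - p)) / (L / 2))^2))
}

#' Exact (Clopper-Pearson) 95% binomial interval
#'
#' Exact binomial confidence interval via Beta quantiles, with endpoints 0
#' and 1 at the boundary cases.
#'
#' @param successes Number of successes (0..trials).
#' @param trials Number of trials (> 0).
#' @return Numeric vector `c(lower, upper)` on the probability scale.
#' @examples
#' round(100 * clopper_pearson(0, 1000), 1) # 0.0 0.4
#' @export
clopper_pearson <- function(successes, trials) {
  stopifnot(length(successes) == 1L, length(trials) == 1L)
  if (trials <= 0 || successes < 0 || successes > trials) {
    stop("need 0 <= successes <= trials with trials > 0")
  }
  lower <- if (successes == 0) 0 else
    stats::qbeta(0.025, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    stats::qbeta(0.975, successes + 1, trials - successes)
  c(lower = lower, upper = upper)
}

#' Mean with MCSE-based 95% Monte Carlo interval
#'
#' The Monte Carlo standard error of a mean over simulation replicates is
#' `sd / sqrt(n)`; the interval is `mean +/- z_0.975 * MCSE`. Used for bias
#' and coverage summaries.
#'
#' @param values Numeric vector of at least 2 replicate-level values.
#' @return List with `estimate`, `lower`, `upper`, `mcse`.
#' @export
mc_interval_mean <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  mcse <- stats::sd(values) / sqrt(length(values))
  list(estimate = m, lower = m - z975() * mcse, upper = m + z975() * mcse,
       mcse = mcse)
}

detection_row <- function(hits, n) {
  ci <- clopper_pearson(hits, n)
  data.frame(rate = 100 * hits / n, lower = 100 * ci[["lower"]],
             upper = 100 * ci[["upper"]], n = n)
}

#' Aggregate replicate-level results for one scenario
#'
#' Computes the scenario's performance measures from the flat replicate
#' table produced by [run_study()]: per-tool detection percentages (overall
#' and per test pair) with Clopper-Pearson 95% Monte Carlo intervals, bias
#' of the nine posterior-median estimates (mean with MCSE interval, plus
#' median with 2.5th/97.5th percentiles), and 95% credible interval
#' coverage. The residual-plot "overall" detection is the rate at which any
#' of the six pairwise residual flags fires. Denominators are always the
#' converged replicates.
#'
#' @param replicates Data frame of replicate rows for a single scenario
#'   (see [run_study()] for the column contract).
#' @param truth The generating [scenario()] object.
#' @return An object of class `scenario_performance` with components
#'   `scenario`, `counts` (replicate accounting), `detect_overall`,
#'   `detect_pairwise`, `bias`, and `coverage`.
#' @export
aggregate_scenario <- function(replicates, truth) {
  stopifnot(is.data.frame(replicates))
  n_sim <- nrow(replicates)
  conv <- replicates[replicates$converged %in% TRUE, , drop = FALSE]
  n_conv <- nrow(conv)
  accounting <- list(n_sim = n_sim, n_converged = n_conv,
                     n_excluded = n_sim - n_conv,
                     n_degenerate = sum(!conv$residuals_defined))
  if (n_conv == 0L) {
    out <- structure(list(scenario = truth, counts = accounting,
                          detect_overall = NULL, detect_pairwise = NULL,
                          bias = NULL, coverage = NULL,
                          no_estimate = TRUE),
                     class = "scenario_performance")
    return(out)
  }

  pairs <- pair_names()
  tools <- c(resid = "resid_flag", g2 = "pw_g2_flag", chi2 = "pw_chi2_flag")

  # overall detection: residual plot = any pairwise residual flag; chi2/G2
  # use the 16-cell statistics against the df = 6 critical value
  resid_cols <- paste0("resid_flag_", pairs)
  defined <- conv$residuals_defined %in% TRUE
  any_resid <- rowSums(conv[resid_cols] == TRUE, na.rm = TRUE) > 0
  detect_overall <- rbind(
    cbind(tool = "residual_plot", detection_row(sum(any_resid[defined]), sum(defined))),
    cbind(tool = "overall_g2", detection_row(sum(conv$overall_g2_flag), n_conv)),
    cbind(tool = "overall_chi2", detection_row(sum(conv$overall_chi2_flag), n_conv)))

  detect_pairwise <- do.call(rbind, lapply(names(tools), function(tl) {
    do.call(rbind, lapply(pairs, function(pr) {
      col <- paste0(tools[[tl]], "_", pr)
      vals <- conv[[col]]
      if (tl == "resid") vals <- vals[defined]
      cbind(tool = tl, pair = pr, detection_row(sum(vals, na.rm = TRUE), length(vals)))
    }))
  }))
  detect_pairwise$tool <- c(resid = "residual_plot", g2 = "pairwise_g2",
                            chi2 = "pairwise_chi2")[detect_pairwise$tool]

  true_vals <- c(truth$prevalence, truth$sensitivities, truth$specificities)
  pars <- lcm_par_names()
  bias <- do.call(rbind, lapply(seq_along(pars), function(i) {
    est <- conv[[paste0("est_", pars[i])]]
    b <- est - true_vals[i]
    mi <- mc_interval_mean(b)
    qs <- stats::quantile(b, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(parameter = pars[i], truth = true_vals[i],
               mean_bias = mi$estimate, lower = mi$lower, upper = mi$upper,
               median_bias = qs[2], p2.5 = qs[1], p97.5 = qs[3])
  }))

  coverage <- do.call(rbind, lapply(seq_along(pars), function(i) {
    lo <- conv[[paste0("cri_low_", pars[i])]]
    hi <- conv[[paste0("cri_high_", pars[i])]]
    hit <- sum(lo <= true_vals[i] & true_vals[i] <= hi)
    cbind(parameter = pars[i], detection_row(hit, n_conv))
  }))
  names(coverage)[names(coverage) == "rate"] <- "coverage"

  structure(list(scenario = truth, counts = accounting,
                 detect_overall = detect_overall,
                 detect_pairwise = detect_pairwise,
                 bias = bias, coverage = coverage, no_estimate = FALSE),
            class = "scenario_performance")
}

#' @export
print.scenario_performance <- function(x, ...) {
  cat("Performance for scenario", x$scenario$label, "\n")
  cat(sprintf("  replicates: %d simulated, %d converged, %d excluded\n",
              x$counts$n_sim, x$counts$n_converged, x$counts$n_excluded))
  if (isTRUE(x$no_estimate)) {
    cat("  no converged replicates: no estimates available\n")
    return(invisible(x))
  }
  cat("  overall lack-of-fit detection (%):\n")
  print(x$detect_overall, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Pool replicate-level results across scenarios
#'
#' Pooled detection percentages and bias percentile summaries over all
#' converged replicates in each group, computed from the flat replicate
#' table (not by averaging per-scenario summaries). Grouping mirrors the
#' study's cross-scenario summaries: everything pooled, or split by
#' prevalence, dependence fraction omega, or sample size.
#'
#' @param replicates Flat replicate table from [run_study()] covering one or
#'   more scenarios.
#' @param truth_table Data frame from [grid_as_data_frame()] for the
#'   scenarios involved (used for true parameter values and group keys).
#' @param grouping One of "all", "pi", "omega", "n_obs".
#' @return A list with `detect_overall`, `detect_pairwise` (percentages with
#'   Clopper-Pearson intervals) and `bias` (median, 2.5th, 97.5th
#'   percentiles) per group.
#' @export
aggregate_across_scenarios <- function(replicates, truth_table,
                                       grouping = c("all", "pi", "omega", "n_obs")) {
  grouping <- match.arg(grouping)
  stopifnot(nrow(replicates) > 0L)
  key_cols <- c(pi = "pi", omega = "omega", n_obs = "n_obs")
  merged <- merge(replicates, truth_table, by = "label", sort = FALSE)
  if (nrow(merged) != nrow(replicates)) stop("replicates reference unknown scenarios")
  group <- if (grouping == "all") rep("all", nrow(merged)) else
    as.character(merged[[key_cols[[grouping]]]])

  pars <- lcm_par_names()
  truth_cols <- c("pi", paste0("se", 1:4), paste0("sp", 1:4))
  per_group <- lapply(split(seq_len(nrow(merged)), group), function(idx) {
    g <- merged[idx, , drop = FALSE]
    conv <- g[g$converged %in% TRUE, , drop = FALSE]
    if (nrow(conv) == 0L) stop("group has no converged replicates")
    defined <- conv$residuals_defined %in% TRUE
    resid_cols <- paste0("resid_flag_", pair_names())
    any_resid <- rowSums(conv[resid_cols] == TRUE, na.rm = TRUE) > 0
    detect_overall <- rbind(
      cbind(tool = "residual_plot",
            detection_row(sum(any_resid[defined]), sum(defined))),
      cbind(tool = "overall_g2", detection_row(sum(conv$overall_g2_flag), nrow(conv))),
      cbind(tool = "overall_chi2", detection_row(sum(conv$overall_chi2_flag), nrow(conv))))
    detect_pairwise <- do.call(rbind, lapply(pair_names(), function(pr) {
      rbind(
        cbind(tool = "residual_plot", pair = pr,
              detection_row(sum(conv[[paste0("resid_flag_", pr)]][defined],
                                na.rm = TRUE), sum(defined))),
        cbind(tool = "pairwise_g2", pair = pr,
              detection_row(sum(conv[[paste0("pw_g2_flag_", pr)]]), nrow(conv))),
        cbind(tool = "pairwise_chi2", pair = pr,
              detection_row(sum(conv[[paste0("pw_chi2_flag_", pr)]]), nrow(conv))))
    }))
    bias <- do.call(rbind, lapply(seq_along(pars), function(i) {
      b <- conv[[paste0("est_", pars[i])]] - conv[[truth_cols[i]]]
      qs <- stats::quantile(b, c(0.025, 0.5, 0.975), names = FALSE)
      data.frame(parameter = pars[i], median_bias = qs[2],
                 p2.5 = qs[1], p97.5 = qs[3], n = nrow(conv))
    }))
    list(detect_overall = detect_overall, detect_pairwise = detect_pairwise,
         bias = bias)
  })
  per_group
}
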