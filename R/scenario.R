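#' Upper bound on the within-diseased covariance between tests 1 and 2
#'
#' The fixed-effect conditional-dependence model adds a positive covariance
#' `covse12 = Cov(T1, T2 | D = 1)` to the joint probability of the first two
#' test results in the diseased class. For all 16 pattern probabilities to
#' remain valid the covariance cannot exceed `min(se1, se2) - se1 * se2`.
#'
#' @param se1,se2 Sensitivities of tests 1 and 2, each strictly in (0, 1).
#' @return The maximum admissible covariance (a nonnegative number).
#' @examples
#' max_covariance(0.9, 0.9) # 0.09
#' max_covariance(0.6, 0.6) # 0.24
#' @export
max_covariance <- function(se1, se2) {
  stopifnot(is.numeric(se1), is.numeric(se2), length(se1) == 1L, length(se2) == 1L)
  if (se1 <= 0 || se1 >= 1 || se2 <= 0 || se2 >= 1) {
    stop("sensitivities must be strictly inside (0, 1)")
  }
  min(se1, se2) - se1 * se2
}

#' Define one simulation scenario
#'
#' A scenario is one point of the data-generating grid: prevalence, the four
#' sensitivities and specificities, the dependence fraction `omega`, and the
#' sample size. The covariance between tests 1 and 2 in the diseased class is
#' derived as `omega` times the maximum admissible covariance, so `omega`
#' equals the conditional Pearson correlation whenever `Se1 == Se2`.
#'
#' @param prevalence Probability of disease, strictly in (0, 1).
#' @param sensitivities Numeric vector of 4 sensitivities in (0, 1).
#' @param specificities Numeric vector of 4 specificities in (0, 1).
#' @param omega Fraction of the maximum admissible covariance, in \\[0, 1).
#' @param n_obs Number of study subjects (positive integer).
#' @param label Optional scenario label; derived from H/L letter codes
#'   (H = 0.9, L = 0.6) when all accuracies are at those two levels.
#' @return An object of class `lcm_scenario`.
#' @examples
#' sc <- scenario(0.5, rep(0.9, 4), rep(0.9, 4), omega = 0.5, n_obs = 2000)
#' sc$covse12 # 0.045
#' @export
scenario <- function(prevalence, sensitivities, specificities, omega,
                     n_obs, label = NULL) {
  stopifnot(length(sensitivities) == 4L, length(specificities) == 4L,
            length(prevalence) == 1L, length(omega) == 1L, length(n_obs) == 1L)
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  if (any(sensitivities <= 0 | sensitivities >= 1)) {
    stop("all sensitivities must be in (0, 1)")
  }
  if (any(specificities <= 0 | specificities >= 1)) {
    stop("all specificities must be in (0, 1)")
  }
  if (omega < 0 || omega >= 1) stop("omega must be in [0, 1)")
  if (n_obs < 1 || n_obs != round(n_obs)) stop("n_obs must be a positive integer")
  covse12 <- omega * max_covariance(sensitivities[1], sensitivities[2])
  if (is.null(label)) label <- scenario_label(sensitivities, specificities)
  structure(
    list(prevalence = prevalence,
         sensitivities = as.numeric(sensitivities),
         specificities = as.numeric(specificities),
         omega = omega,
         covse12 = covse12,
         n_obs = as.integer(n_obs),
         label = label),
    class = "lcm_scenario")
}

#' @export
print.lcm_scenario <- function(x, ...) {
  cat("Latent class simulation scenario ", x$label, "\n", sep = "")
  cat(sprintf("  prevalence %.3g, omega %.3g (covse12 = %.4g), n_obs %d\n",
              x$prevalence, x$omega, x$covse12, x$n_obs))
  cat("  Se:", paste(format(x$sensitivities), collapse = " "), "\n")
  cat("  Sp:", paste(format(x$specificities), collapse = " "), "\n")
  invisible(x)
}

# H/L letter code for one accuracy vector; values away from 0.9/0.6 fall
# back to a numeric code.
accuracy_code <- function(values) {
  letters <- vapply(values, function(v) {
    if (isTRUE(all.equal(v, 0.9))) "H"
    else if (isTRUE(all.equal(v, 0.6))) "L"
    else sprintf("(%.3g)", v)
  }, character(1))
  paste(letters, collapse = "")
}

scenario_label <- function(sensitivities, specificities) {
  paste0(accuracy_code(sensitivities), "-", accuracy_code(specificities))
}

# Accuracy combinations of the study grid: H = 0.9, L = 0.6. Tests 1 and 2
# always share the same sensitivity level so that omega is interpretable as
# the conditional Pearson correlation.
se_combinations <- function() {
  list(c("H", "H", "L", "L"), c("H", "H", "H", "L"), c("H", "H", "H", "H"),
       c("L", "L", "L", "L"), c("L", "L", "H", "L"), c("L", "L", "H", "H"))
}

sp_combinations <- function() {
  c(se_combinations(), list(c("L", "H", "L", "H")))
}

letters_to_values <- function(code) ifelse(code == "H", 0.9, 0.6)

#' Enumerate the full simulation grid
#'
#' Crosses sample size (500, 2000, 5000), prevalence (0.2, 0.5), the six
#' sensitivity combinations, the seven specificity combinations and
#' omega (0.5, 0.9), giving 504 scenarios.
#'
#' @return A list of [scenario()] objects of length 504.
#' @examples
#' grid <- build_full_grid()
#' length(grid) # 504
#' @export
build_full_grid <- function() {
  grid <- list()
  for (n_obs in c(500L, 2000L, 5000L)) {
    for (pi in c(0.2, 0.5)) {
      for (se in se_combinations()) {
        for (sp in sp_combinations()) {
          for (omega in c(0.5, 0.9)) {
            grid[[length(grid) + 1L]] <- scenario(
              prevalence = pi,
              sensitivities = letters_to_values(se),
              specificities = letters_to_values(sp),
              omega = omega, n_obs = n_obs)
          }
        }
      }
    }
  }
  grid
}

#' Flatten scenarios into a data frame
#'
#' One row per scenario with columns `label, pi, se1..se4, sp1..sp4, omega,
#' covse12, n_obs`, suitable for export with [utils::write.csv()].
#'
#' @param scenarios A list of [scenario()] objects (or a single one).
#' @return A data.frame with one row per scenario.
#' @export
grid_as_data_frame <- function(scenarios) {
  if (inherits(scenarios, "lcm_scenario")) scenarios <- list(scenarios)
  rows <- lapply(scenarios, function(s) {
    data.frame(label = s$label, pi = s$prevalence,
               se1 = s$sensitivities[1], se2 = s$sensitivities[2],
               se3 = s$sensitivities[3], se4 = s$sensitivities[4],
               sp1 = s$specificities[1], sp2 = s$specificities[2],
               sp3 = s$specificities[3], sp4 = s$specificities[4],
               omega = s$omega, covse12 = s$covse12, n_obs = s$n_obs,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Conditional Pearson correlation implied by a scenario
#'
#' The covariance `covse12` between tests 1 and 2 in the diseased class
#' corresponds to a Pearson correlation
#' `covse12 / sqrt(Se1 (1 - Se1) Se2 (1 - Se2))`; when `Se1 == Se2` this
#' equals the scenario's `omega`.
#'
#' @param scenario An [scenario()] object.
#' @return The conditional Pearson correlation between T1 and T2 given D = 1.
#' @export
implied_correlation <- function(scenario) {
  se <- scenario$sensitivities
  scenario$covse12 / sqrt(se[1] * (1 - se[1]) * se[2] * (1 - se[2]))
}
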