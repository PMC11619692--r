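lcm_par_names <- function() c("pi", paste0("Se", 1:4), paste0("Sp", 1:4))

#' MCMC sampler settings
#'
#' Defaults follow the study protocol: 3 chains, 5000 burn-in sweeps and
#' 10000 retained sweeps per chain; a fit is flagged non-converged when any
#' parameter has R-hat above 1.1 or an effective sample size below 400
#' (equivalent to a Monte Carlo error above 5% of the posterior SD).
#'
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param n_burnin Burn-in sweeps discarded per chain.
#' @param n_iter Retained sweeps per chain.
#' @param rhat_threshold Exclusion threshold on R-hat (> 1).
#' @param neff_threshold Exclusion threshold on the effective sample size.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 3L, n_burnin = 5000L, n_iter = 10000L,
                          rhat_threshold = 1.1, neff_threshold = 400) {
  stopifnot(n_chains >= 1, n_burnin >= 1, n_iter >= 1,
            rhat_threshold > 1, neff_threshold > 0)
  structure(list(n_chains = as.integer(n_chains),
                 n_burnin = as.integer(n_burnin),
                 n_iter = as.integer(n_iter),
                 rhat_threshold = rhat_threshold,
                 neff_threshold = neff_threshold),
            class = "mcmc_settings")
}

# initial values: independent draws from the Beta(1,1) priors truncated to
# Se_i >= 1 - Sp_i (rejection on the unit square, acceptance probability 1/2)
constrained_prior_init <- function() {
  se <- numeric(4); sp <- numeric(4)
  for (i in 1:4) {
    repeat {
      a <- stats::runif(1); b <- stats::runif(1)
      if (a + b >= 1) { se[i] <- a; sp[i] <- b; break }
    }
  }
  c(stats::runif(1), se, sp)
}

#' Fit the conditional-independence model by Gibbs sampling
#'
#' Bayesian fit of the two-class conditional-independence latent class model
#' to 16-cell pattern counts, with Beta(1,1) priors on prevalence and all
#' sensitivities and specificities, truncated to the constraint
#' `Se_i >= 1 - Sp_i` (which rules out the mirror, label-switched mode).
#' Sampling uses data augmentation on the latent class membership of each
#' cell; all full conditionals are (truncated) Beta distributions. Initial
#' values are drawn independently per chain from the constrained prior so
#' that R-hat is meaningful.
#'
#' @param counts A [pattern_counts()] object (or 16-vector of counts).
#' @param settings An [mcmc_settings()] object.
#' @param seed Optional integer seed for reproducibility.
#' @param fix_allocation Internal validation hook: an integer 16-vector of
#'   per-cell diseased counts; when supplied the latent allocation step is
#'   skipped and the allocation held fixed, collapsing the model to its
#'   conjugate form. Leave `NULL` for normal use.
#' @return An object of class `lcm_posterior`: `chains` (list of
#'   `n_iter` x 9 matrices with columns pi, Se1..Se4, Sp1..Sp4), `rhat` and
#'   `n_eff` per parameter, `converged`, and the settings used.
#' @examples
#' sc <- scenario(0.5, rep(0.9, 4), rep(0.9, 4), omega = 0, n_obs = 500)
#' d <- simulate_dataset(sc, seed = 1)
#' fit <- gibbs_fit(d, mcmc_settings(n_burnin = 200, n_iter = 500), seed = 1)
#' fit$converged
#' @export
gibbs_fit <- function(counts, settings = mcmc_settings(), seed = NULL,
                      fix_allocation = NULL) {
  if (inherits(counts, "pattern_counts")) counts <- counts$counts
  stopifnot(length(counts) == 16L)
  counts <- as.integer(counts)
  if (sum(counts) <= 0L) stop("counts must sum to a positive total")
  if (!is.null(seed)) set.seed(seed)
  fix <- !is.null(fix_allocation)
  fixed_y <- if (fix) as.integer(fix_allocation) else integer(16L)
  if (fix && any(fixed_y > counts)) stop("fixed allocation exceeds cell counts")

  chains <- vector("list", settings$n_chains)
  for (ch in seq_len(settings$n_chains)) {
    init <- constrained_prior_init()
    draws <- .gibbs_chain_cpp(counts, init, settings$n_burnin,
                              settings$n_iter, fix, fixed_y)
    colnames(draws) <- lcm_par_names()
    chains[[ch]] <- draws
  }

  rhat <- n_eff <- stats::setNames(numeric(9L), lcm_par_names())
  if (settings$n_chains >= 2L) {
    for (p in seq_len(9L)) {
      mat <- vapply(chains, function(d) d[, p], numeric(settings$n_iter))
      rhat[p] <- compute_rhat(mat)
      n_eff[p] <- compute_neff(mat)
    }
    converged <- all(rhat <= settings$rhat_threshold) &&
      all(n_eff >= settings$neff_threshold)
  } else {
    rhat[] <- NA_real_; n_eff[] <- NA_real_
    converged <- NA
  }

  structure(list(chains = chains, rhat = rhat, n_eff = n_eff,
                 converged = converged, settings = settings,
                 counts = counts, seed = seed),
            class = "lcm_posterior")
}

#' Pool posterior draws across chains
#'
#' @param fit An `lcm_posterior` object.
#' @return A (chains x iterations) x 9 matrix of pooled draws.
#' @export
pooled_draws <- function(fit) {
  do.call(rbind, fit$chains)
}

#' @export
print.lcm_posterior <- function(x, ...) {
  cat("Bayesian conditional-independence LCM fit\n")
  cat(sprintf("  %d chains x %d retained sweeps (burn-in %d)\n",
              x$settings$n_chains, x$settings$n_iter, x$settings$n_burnin))
  cat(sprintf("  converged: %s (max R-hat %.3f, min n_eff %.0f)\n",
              x$converged, max(x$rhat), min(x$n_eff)))
  print(summarize_posterior(x)$table, digits = 3)
  invisible(x)
}

#' Posterior medians and 95% credible intervals
#'
#' Pooled-across-chains posterior medians and equal-tailed 2.5%/97.5%
#' quantiles for the nine model parameters.
#'
#' @param fit An `lcm_posterior` object.
#' @return A list with `medians`, `cri_low`, `cri_high` (named 9-vectors) and
#'   `table`, a data.frame with one row per parameter.
#' @export
summarize_posterior <- function(fit) {
  draws <- pooled_draws(fit)
  if (nrow(draws) == 0L) stop("no posterior draws to summarize")
  q <- apply(draws, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975),
             names = FALSE)
  medians <- q[2L, ]; lo <- q[1L, ]; hi <- q[3L, ]
  list(medians = medians, cri_low = lo, cri_high = hi,
       table = data.frame(parameter = lcm_par_names(), median = medians,
                          cri_low = lo, cri_high = hi, row.names = NULL))
}
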