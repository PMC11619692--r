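# Independent oracles, written with different machinery than the package
# (expand.grid enumeration over (t1..t4, D) instead of the package's
# pattern-matrix loops) so that agreement between the two routes is a
# genuine check.

# joint probabilities by brute-force enumeration over all results and the
# latent class, with an optional covariance between tests 1 and 2 in D = 1
oracle_pattern_probs <- function(pi, se, sp, cov12 = 0) {
  g <- expand.grid(t4 = 0:1, t3 = 0:1, t2 = 0:1, t1 = 0:1, d = 0:1)
  p <- numeric(16)
  for (r in seq_len(nrow(g))) {
    t <- c(g$t1[r], g$t2[r], g$t3[r], g$t4[r])
    k <- 8 * t[1] + 4 * t[2] + 2 * t[3] + t[4] + 1
    if (g$d[r] == 1) {
      p12 <- prod(ifelse(t[1:2] == 1, se[1:2], 1 - se[1:2])) +
        (-1)^(t[1] - t[2]) * cov12
      contrib <- pi * p12 * prod(ifelse(t[3:4] == 1, se[3:4], 1 - se[3:4]))
    } else {
      contrib <- (1 - pi) * prod(ifelse(t == 1, 1 - sp, sp))
    }
    p[k] <- p[k] + contrib
  }
  p
}

# agreement P(Ti = Tj) by the same enumeration
oracle_agreement <- function(pi, se, sp, cov12, pair) {
  g <- expand.grid(t4 = 0:1, t3 = 0:1, t2 = 0:1, t1 = 0:1)
  p <- oracle_pattern_probs(pi, se, sp, cov12)
  t_i <- g[[paste0("t", pair[1])]]
  t_j <- g[[paste0("t", pair[2])]]
  k <- 8 * g$t1 + 4 * g$t2 + 2 * g$t3 + g$t4 + 1
  sum(p[k][t_i == t_j])
}

# random-walk Metropolis sampler targeting the same posterior as gibbs_fit:
# multinomial likelihood over the 16 cells, flat priors on the constrained
# region {Se_i + Sp_i >= 1}. Independent of the Gibbs code path.
oracle_rwm_fit <- function(counts, n_iter = 60000, sd_prop = 0.015,
                           init = rep(0.7, 9)) {
  log_post <- function(th) {
    if (any(th <= 0) || any(th >= 1)) return(-Inf)
    if (any(th[2:5] + th[6:9] < 1)) return(-Inf)
    p <- oracle_pattern_probs(th[1], th[2:5], th[6:9])
    sum(counts * log(p))
  }
  th <- init
  lp <- log_post(th)
  out <- matrix(NA_real_, n_iter, 9)
  for (i in seq_len(n_iter)) {
    cand <- th + stats::rnorm(9, 0, sd_prop)
    lp_c <- log_post(cand)
    if (log(stats::runif(1)) < lp_c - lp) { th <- cand; lp <- lp_c }
    out[i, ] <- th
  }
  colnames(out) <- c("pi", paste0("Se", 1:4), paste0("Sp", 1:4))
  out[-seq_len(n_iter %/% 4), ]  # drop burn-in quarter
}

# reduced sampler settings for fast unit tests (the study defaults are used
# in the acceptance runs)
quick_mcmc <- function() mcmc_settings(n_chains = 3, n_burnin = 500, n_iter = 1500)
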