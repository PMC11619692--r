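# Fixed pattern convention: the 16 joint results of four binary tests are
# indexed k = 8 t1 + 4 t2 + 2 t3 + t4 (t1 most significant), k = 0..15,
# stored in R vectors at position k + 1.

#' Matrix of the 16 four-test result patterns
#'
#' Rows follow the package's pattern order, index `k = 8 t1 + 4 t2 + 2 t3 +
#' t4` at row `k + 1`; columns are tests 1 to 4.
#'
#' @return A 16 x 4 integer matrix of 0/1 results.
#' @export
pattern_matrix <- function() {
  k <- 0:15
  m <- cbind(t1 = k %/% 8L %% 2L, t2 = k %/% 4L %% 2L,
             t3 = k %/% 2L %% 2L, t4 = k %% 2L)
  m
}

#' Pattern probabilities under conditional independence
#'
#' Joint probability of every four-test result pattern under the two-class
#' model in which tests are mutually independent given the latent disease
#' status: `pi * prod_i Se_i^t_i (1-Se_i)^(1-t_i) +
#' (1-pi) * prod_i Sp_i^(1-t_i) (1-Sp_i)^t_i`.
#'
#' @param prevalence Disease prevalence in (0, 1).
#' @param sensitivities,specificities Numeric vectors of 4 probabilities in (0, 1).
#' @return Numeric vector of 16 probabilities summing to 1, in pattern order.
#' @examples
#' p <- cind_pattern_probs(0.5, rep(0.9, 4), rep(0.9, 4))
#' sum(p) # 1
#' @export
cind_pattern_probs <- function(prevalence, sensitivities, specificities) {
  stopifnot(length(sensitivities) == 4L, length(specificities) == 4L)
  if (any(c(prevalence, sensitivities, specificities) <= 0) ||
      any(c(prevalence, sensitivities, specificities) >= 1)) {
    stop("all parameters must be strictly inside (0, 1)")
  }
  tm <- pattern_matrix()
  dis <- apply(tm, 1L, function(t) prod(sensitivities^t * (1 - sensitivities)^(1 - t)))
  hea <- apply(tm, 1L, function(t) prod(specificities^(1 - t) * (1 - specificities)^t))
  prevalence * dis + (1 - prevalence) * hea
}

#' Pattern probabilities under the conditional-dependence generating model
#'
#' As [cind_pattern_probs()] but with a fixed-effect covariance `covse12`
#' between tests 1 and 2 in the diseased class: the Se-product over the first
#' two tests gains `(-1)^(t1 - t2) * covse12`, i.e. the covariance is added
#' when the two results agree and subtracted when they disagree. Tests 3 and
#' 4, and everything in the disease-free class, remain conditionally
#' independent.
#'
#' @param scenario A [scenario()] object (its `covse12` must respect the
#'   admissibility bound, which [scenario()] guarantees).
#' @return Numeric vector of 16 probabilities summing to 1, in pattern order.
#' @examples
#' sc <- scenario(0.5, rep(0.9, 4), rep(0.9, 4), omega = 0.5, n_obs = 2000)
#' p <- cdep_pattern_probs(sc)
#' # agreement P(T1 = T2) is lifted from 0.82 to 0.865 by the dependence
#' sum(p[pattern_matrix()[, 1] == pattern_matrix()[, 2]])
#' @export
cdep_pattern_probs <- function(scenario) {
  se <- scenario$sensitivities; sp <- scenario$specificities
  pi <- scenario$prevalence; cov12 <- scenario$covse12
  tm <- pattern_matrix()
  p <- numeric(16L)
  for (k in seq_len(16L)) {
    t <- tm[k, ]
    se12 <- prod(se[1:2]^t[1:2] * (1 - se[1:2])^(1 - t[1:2])) +
      (-1)^(t[1] - t[2]) * cov12
    se34 <- prod(se[3:4]^t[3:4] * (1 - se[3:4])^(1 - t[3:4]))
    hea <- prod(sp^(1 - t) * (1 - sp)^t)
    p[k] <- pi * se12 * se34 + (1 - pi) * hea
  }
  if (any(p < 0)) {
    bad <- which(p < 0)[1L]
    stop(sprintf(
      "negative probability for pattern (t1,t2,t3,t4) = (%s): covariance bound violated",
      paste(tm[bad, ], collapse = ",")))
  }
  p
}

#' Container for 16-cell pattern counts
#'
#' A simulated (or observed) data set is stored as the counts of the 16 test
#' result patterns -- the sufficient statistic for every computation in the
#' package.
#'
#' @param counts Integer vector of 16 nonnegative counts in pattern order.
#' @param seed_info Optional record of the RNG seed/stream that produced them.
#' @return An object of class `pattern_counts`.
#' @export
pattern_counts <- function(counts, seed_info = NULL) {
  stopifnot(length(counts) == 16L)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  structure(list(counts = as.integer(counts),
                 n_obs = as.integer(sum(counts)),
                 seed_info = seed_info),
            class = "pattern_counts")
}

#' @export
print.pattern_counts <- function(x, ...) {
  cat("Pattern counts over 16 four-test result patterns, n_obs =", x$n_obs, "\n")
  print(stats::setNames(x$counts, apply(pattern_matrix(), 1L, paste, collapse = "")))
  invisible(x)
}

#' Simulate one data set from a scenario
#'
#' Draws the 16 pattern counts from a multinomial distribution with the exact
#' conditional-dependence pattern probabilities of the scenario.
#'
#' @param scenario A [scenario()] object.
#' @param seed Optional integer seed; when given, `set.seed(seed)` is called
#'   first and recorded in the result, making the draw reproducible.
#' @return A [pattern_counts()] object with `n_obs` equal to the scenario's.
#' @export
simulate_dataset <- function(scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  probs <- cdep_pattern_probs(scenario)
  counts <- as.integer(stats::rmultinom(1L, size = scenario$n_obs, prob = probs))
  pattern_counts(counts, seed_info = list(seed = seed, label = scenario$label))
}

# Index pairs (i, j), i < j, in the package's fixed pair order.
test_pairs <- function() {
  list(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L), c(3L, 4L))
}

pair_names <- function() {
  vapply(test_pairs(), function(p) sprintf("T%dxT%d", p[1], p[2]), character(1))
}

#' Pairwise agreement probabilities
#'
#' For each of the six test pairs, the probability (or observed fraction)
#' that the two tests agree, `P(T_i = T_j)`, obtained by summing over the
#' eight patterns with `t_i == t_j`.
#'
#' @param source Either a numeric vector of 16 pattern probabilities or a
#'   [pattern_counts()] object.
#' @return Named numeric vector of 6 agreement probabilities, pair order
#'   (1,2), (1,3), (1,4), (2,3), (2,4), (3,4).
#' @examples
#' agreement_probabilities(cind_pattern_probs(0.5, rep(0.9, 4), rep(0.9, 4)))
#' @export
agreement_probabilities <- function(source) {
  if (inherits(source, "pattern_counts")) {
    p <- source$counts / source$n_obs
  } else {
    stopifnot(is.numeric(source), length(source) == 16L)
    p <- source
  }
  tm <- pattern_matrix()
  out <- vapply(test_pairs(), function(pr) {
    sum(p[tm[, pr[1]] == tm[, pr[2]]])
  }, numeric(1))
  stats::setNames(out, pair_names())
}
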