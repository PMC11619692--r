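# End-to-end orchestration: scenario grid -> simulate -> fit -> assess ->
# aggregate, with per-replicate derived seeds, optional on-disk
# checkpointing and desk-scale presets.

#' Study configuration
#'
#' @param scenarios List of [scenario()] objects (or a single one).
#' @param n_sim Replicates per scenario (the full study protocol uses 1000).
#' @param mcmc An [mcmc_settings()] object.
#' @param root_seed Integer root seed; every replicate derives its own seed
#'   from it, so any execution order gives identical results.
#' @param output_dir Optional directory for checkpointed replicate tables;
#'   `NULL` keeps everything in memory.
#' @return An object of class `study_config`.
#' @export
study_config <- function(scenarios, n_sim = 1000L, mcmc = mcmc_settings(),
                         root_seed = 20240101L, output_dir = NULL) {
  if (inherits(scenarios, "lcm_scenario")) scenarios <- list(scenarios)
  stopifnot(length(scenarios) >= 1L, n_sim >= 1L,
            inherits(mcmc, "mcmc_settings"))
  if (!all(vapply(scenarios, inherits, logical(1), "lcm_scenario"))) {
    stop("scenarios must be lcm_scenario objects")
  }
  structure(list(scenarios = scenarios, n_sim = as.integer(n_sim),
                 mcmc = mcmc, root_seed = as.integer(root_seed),
                 output_dir = output_dir),
            class = "study_config")
}

# deterministic per-replicate seed derived from the root seed, the scenario
# position and the replicate index; kept inside the 32-bit integer range
replicate_seed <- function(root_seed, scenario_index, rep_index) {
  base <- (as.double(root_seed) * 48271 +
             as.double(scenario_index) * 69621 +
             as.double(rep_index) * 16807) %% 2147483629
  as.integer(base) + 1L
}

#' Desk-scale study presets
#'
#' Named single-scenario configurations matching illustrative rows of the
#' study (prevalence 0.5, omega 0.5, n_obs 2000) at a reduced replicate
#' count, each runnable on one CPU in minutes:
#' \describe{
#'   \item{"table6-LLHH-LLHH"}{Se = Sp = (0.6, 0.6, 0.9, 0.9); residual flags
#'     concentrate on the truly dependent pair T1xT2.}
#'   \item{"table6-HHHH-HHHH"}{all accuracies 0.9; flags concentrate,
#'     counterintuitively, on T3xT4.}
#'   \item{"table4-HHHH-HHLL"}{Se all 0.9, Sp = (0.9, 0.9, 0.6, 0.6); the
#'     residual plot detects overall misfit about two-thirds of the time.}
#' }
#'
#' @param name Preset name.
#' @param n_sim Replicates (default 100).
#' @param root_seed Root seed.
#' @return A [study_config()] object.
#' @export
study_preset <- function(name = c("table6-LLHH-LLHH", "table6-HHHH-HHHH",
                                  "table4-HHHH-HHLL"),
                         n_sim = 100L, root_seed = 20240101L) {
  name <- match.arg(name)
  acc <- switch(name,
    "table6-LLHH-LLHH" = list(se = c(0.6, 0.6, 0.9, 0.9), sp = c(0.6, 0.6, 0.9, 0.9)),
    "table6-HHHH-HHHH" = list(se = rep(0.9, 4), sp = rep(0.9, 4)),
    "table4-HHHH-HHLL" = list(se = rep(0.9, 4), sp = c(0.9, 0.9, 0.6, 0.6)))
  sc <- scenario(prevalence = 0.5, sensitivities = acc$se,
                 specificities = acc$sp, omega = 0.5, n_obs = 2000L)
  study_config(sc, n_sim = n_sim, root_seed = root_seed)
}

# one replicate: simulate, fit, assess; returns a flat one-row data.frame
run_replicate <- function(sc, rep_index, seed, mcmc) {
  data <- simulate_dataset(sc, seed = seed)
  fit <- gibbs_fit(data, settings = mcmc)  # continues the seeded stream
  gof <- assess_fit(data, fit)
  summ <- summarize_posterior(fit)
  pars <- lcm_par_names(); pairs <- pair_names()
  row <- data.frame(label = sc$label, rep = rep_index, seed = seed,
                    converged = fit$converged,
                    residuals_defined = all(gof$residuals$defined),
                    overall_chi2 = gof$overall$chi2,
                    overall_g2 = gof$overall$g2,
                    overall_chi2_flag = gof$overall$chi2_flag,
                    overall_g2_flag = gof$overall$g2_flag)
  for (p in seq_along(pairs)) {
    row[[paste0("resid_median_", pairs[p])]] <- gof$residuals$median[p]
    row[[paste0("resid_flag_", pairs[p])]] <- gof$residuals$flag[p]
    row[[paste0("pw_chi2_flag_", pairs[p])]] <- gof$pairwise$chi2_flag[p]
    row[[paste0("pw_g2_flag_", pairs[p])]] <- gof$pairwise$g2_flag[p]
  }
  for (i in seq_along(pars)) {
    row[[paste0("est_", pars[i])]] <- summ$medians[i]
    row[[paste0("cri_low_", pars[i])]] <- summ$cri_low[i]
    row[[paste0("cri_high_", pars[i])]] <- summ$cri_high[i]
  }
  row
}

#' Run a simulation study
#'
#' For every scenario and replicate of the configuration: simulate a data
#' set, fit the conditional-independence model, assess its fit, and collect
#' one flat row per replicate. Each replicate owns a seed derived from the
#' root seed, so reruns (and any execution order) are byte-identical. With
#' an `output_dir`, per-scenario replicate tables are checkpointed as CSV
#' and completed replicates are skipped on resume.
#'
#' @param config A [study_config()] object.
#' @param progress Print per-scenario progress messages.
#' @return A list with `replicates` (flat data frame, one row per
#'   scenario x replicate) and `performance` (list of
#'   [aggregate_scenario()] results keyed by scenario label).
#' @export
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  use_disk <- !is.null(config$output_dir)
  if (use_disk && !dir.exists(config$output_dir)) {
    ok <- dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", config$output_dir)
  }
  all_rows <- list()
  performance <- list()
  for (s in seq_along(config$scenarios)) {
    sc <- config$scenarios[[s]]
    ckpt <- if (use_disk) {
      file.path(config$output_dir,
                sprintf("replicates_%s_n%d_seed%d.csv",
                        gsub("[^A-Za-z0-9-]", "", sc$label), sc$n_obs,
                        config$root_seed))
    } else NULL
    existing <- NULL
    if (use_disk && file.exists(ckpt)) {
      existing <- utils::read.csv(ckpt, stringsAsFactors = FALSE)
    }
    rows <- list()
    n_excl <- 0L
    for (r in seq_len(config$n_sim)) {
      if (!is.null(existing) && r %in% existing$rep) {
        rows[[r]] <- existing[existing$rep == r, , drop = FALSE]
      } else {
        seed <- replicate_seed(config$root_seed, s, r)
        rows[[r]] <- run_replicate(sc, r, seed, config$mcmc)
        if (use_disk) {
          utils::write.table(rows[[r]], ckpt, sep = ",", row.names = FALSE,
                             col.names = !file.exists(ckpt), append = file.exists(ckpt))
        }
      }
      if (!isTRUE(rows[[r]]$converged)) n_excl <- n_excl + 1L
    }
    reps <- do.call(rbind, rows)
    if (progress) {
      message(sprintf("scenario %s (n_obs %d): %d/%d converged, %d excluded",
                      sc$label, sc$n_obs, config$n_sim - n_excl,
                      config$n_sim, n_excl))
    }
    all_rows[[s]] <- reps
    performance[[sc$label]] <- aggregate_scenario(reps, sc)
  }
  list(replicates = do.call(rbind, all_rows), performance = performance)
}

#' Analytic and fitted pairwise agreement table
#'
#' For each scenario, the six pairwise agreement probabilities `P(Ti = Tj)`:
#' as generated (exact, under the conditional-dependence model), under the
#' "true conditional-independence" reference (same parameters, dependence
#' removed), and -- when fitted posterior medians are supplied -- under the
#' fitted model.
#'
#' @param scenarios List of [scenario()] objects (or a single one).
#' @param fitted_medians Optional list (parallel to `scenarios`) of named
#'   9-vectors of posterior medians.
#' @return Data frame with columns `label`, `source` (observed / true_cind /
#'   fitted) and the six pair columns.
#' @export
run_agreement_table <- function(scenarios, fitted_medians = NULL) {
  if (inherits(scenarios, "lcm_scenario")) scenarios <- list(scenarios)
  rows <- list()
  for (s in seq_along(scenarios)) {
    sc <- scenarios[[s]]
    obs <- agreement_probabilities(cdep_pattern_probs(sc))
    cind <- agreement_probabilities(
      cind_pattern_probs(sc$prevalence, sc$sensitivities, sc$specificities))
    rows[[length(rows) + 1L]] <- data.frame(label = sc$label, source = "observed",
                                            t(obs), check.names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(label = sc$label, source = "true_cind",
                                            t(cind), check.names = FALSE)
    if (!is.null(fitted_medians)) {
      m <- fitted_medians[[s]]
      fitted <- agreement_probabilities(cind_pattern_probs(m[1], m[2:5], m[6:9]))
      rows[[length(rows) + 1L]] <- data.frame(label = sc$label, source = "fitted",
                                              t(fitted), check.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
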