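#' Simulate patient outcomes at a dose
#'
#' Efficacy and toxicity events are independent Bernoulli draws with the
#' scenario's true probabilities at the given dose, matching the
#' independence probability model.
#'
#' @param scenario A scenario (see [builtin_scenarios()]).
#' @param dose_index Dose at which the patients are treated.
#' @param n Number of patients.
#' @return A list with binary vectors `y_eff` and `y_tox`.
#' @export
simulate_outcomes <- function(scenario, dose_index, n) {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  list(y_eff = stats::rbinom(n, 1, scenario$true_eff[dose_index]),
       y_tox = stats::rbinom(n, 1, scenario$true_tox[dose_index]))
}

#' Run one simulated trial
#'
#' Cohorts are treated at the current dose, the posterior is updated after
#' each cohort, and the decision policy picks the next dose (capped by the
#' no-skip rule) or stops the trial.  After the final cohort the same rule
#' set, without the no-skip cap, determines the selected dose; a stopped
#' trial selects no dose.
#'
#' @param scenario A scenario with `true_eff`/`true_tox`.
#' @param design A [design_config()].
#' @param prior A [prior_spec()].
#' @param grid A [dose_grid()].
#' @param seed Integer seed for the whole trial (outcomes and sampler).
#' @param n_draws,burnin Posterior sampler settings per interim.
#' @return An object of class `r2dt_trial`: `selected` (dose index or
#'   `NA`), `patients_per_dose`, `total_n`, `stopped_early`, and a
#'   per-cohort `trace` data frame (cohort, dose, cumulative n, per-dose
#'   expected utilities and admissibility flags).
#' @export
run_trial <- function(scenario, design, prior, grid, seed = NULL,
                      n_draws = 2000, burnin = 1000) {
  stopifnot(inherits(design, "r2dt_design"), inherits(grid, "r2dt_grid"))
  if (!is.null(seed)) set.seed(seed)
  k <- grid$k
  n_cohorts <- design$max_n %/% design$cohort_size
  dose <- design$start_dose_index
  highest_tried <- 0L
  data <- trial_data(k = k)
  stopped <- FALSE
  selected <- NA_integer_
  trace <- vector("list", n_cohorts)

  for (cohort in seq_len(n_cohorts)) {
    out <- simulate_outcomes(scenario, dose, design$cohort_size)
    data <- trial_data(c(data$dose_index, rep(dose, design$cohort_size)),
                       c(data$y_eff, out$y_eff),
                       c(data$y_tox, out$y_tox), k = k)
    highest_tried <- max(highest_tried, dose)

    draws <- sample_posterior(data, prior, grid, n_draws = n_draws,
                              burnin = burnin)
    eu <- posterior_expected_utility(draws, grid, utility = design$utility)
    adm <- .admissibility_flags(draws, grid, design)

    if (cohort == n_cohorts) {
      final <- final_selection(eu, adm, design)
      selected <- final$dose_index
      trace[[cohort]] <- .trace_row(cohort, dose, nrow(data), eu, adm,
                                    final$action)
      break
    }
    dec <- select_dose(eu, adm, highest_tried, design)
    trace[[cohort]] <- .trace_row(cohort, dose, nrow(data), eu, adm,
                                  dec$action)
    if (dec$action == "stop_no_dose") {
      stopped <- TRUE
      break
    }
    dose <- dec$dose_index
  }

  structure(list(
    selected = selected,
    patients_per_dose = tabulate(data$dose_index, nbins = k),
    total_n = nrow(data),
    stopped_early = stopped,
    trace = do.call(rbind, trace[!vapply(trace, is.null, logical(1))])),
    class = "r2dt_trial")
}

.trace_row <- function(cohort, dose, n, eu, adm, action) {
  row <- data.frame(cohort = cohort, dose = dose, n = n, action = action)
  for (j in seq_along(eu)) row[[paste0("eu_d", j)]] <- eu[j]
  for (j in seq_along(adm)) row[[paste0("adm_d", j)]] <- adm[j]
  row
}

#' @export
print.r2dt_trial <- function(x, ...) {
  cat(sprintf("<trial> n = %d%s, selected: %s\n", x$total_n,
              if (x$stopped_early) " (stopped early)" else "",
              if (is.na(x$selected)) "none" else x$selected))
  cat("patients per dose:", paste(x$patients_per_dose, collapse = ", "),
      "\n")
  invisible(x)
}

#' Replicate seeds derived from a master seed
#'
#' Each replicate gets an independent substream seed drawn once from the
#' master seed, so serial runs, pooled half-studies and re-runs of single
#' replicates all agree.
#'
#' @param seed Master seed.
#' @param n_reps Number of replicates.
#' @return Integer vector of length `n_reps`.
#' @export
replicate_seeds <- function(seed, n_reps) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_reps)
}

#' Replicate a trial design and aggregate operating characteristics
#'
#' @inheritParams run_trial
#' @param n_reps Number of simulated trials.
#' @param seed Master seed; per-replicate seeds come from
#'   [replicate_seeds()].
#' @param keep_trials Keep the individual `r2dt_trial` objects in the
#'   result (default `FALSE`).
#' @return An `r2dt_oc` object; see [aggregate_trials()].
#' @export
run_study <- function(scenario, design, prior, grid, n_reps, seed,
                      n_draws = 2000, burnin = 1000, keep_trials = FALSE) {
  seeds <- replicate_seeds(seed, n_reps)
  trials <- lapply(seeds, function(s)
    run_trial(scenario, design, prior, grid, seed = s,
              n_draws = n_draws, burnin = burnin))
  oc <- aggregate_trials(trials, k = grid$k)
  oc$seed <- seed
  if (keep_trials) oc$trials <- trials
  oc
}

#' Aggregate simulated trials into operating characteristics
#'
#' @param trials List of `r2dt_trial` objects.
#' @param k Number of doses.
#' @return An object of class `r2dt_oc`: `pct_selection` (per dose, %),
#'   `pct_nds` (% of trials with no dose selected), `mean_patients` (per
#'   dose, averaged over all replicates including stopped trials),
#'   `mean_total_n` and `n_reps`.
#' @export
aggregate_trials <- function(trials, k) {
  n_reps <- length(trials)
  sel <- vapply(trials, `[[`, integer(1), "selected")
  pat <- do.call(rbind, lapply(trials, `[[`, "patients_per_dose"))
  structure(list(
    pct_selection = vapply(seq_len(k),
                           function(j) 100 * mean(!is.na(sel) & sel == j),
                           numeric(1)),
    pct_nds = 100 * mean(is.na(sel)),
    mean_patients = colMeans(pat),
    mean_total_n = mean(vapply(trials, `[[`, integer(1), "total_n")),
    n_reps = n_reps),
    class = "r2dt_oc")
}

#' @export
print.r2dt_oc <- function(x, ...) {
  cat(sprintf("<operating characteristics> %d replicates\n", x$n_reps))
  tab <- rbind(`% selection` = round(x$pct_selection, 1),
               `mean patients` = round(x$mean_patients, 1))
  colnames(tab) <- paste0("dose", seq_along(x$pct_selection))
  print(tab)
  cat(sprintf("%% no dose selected: %.1f; mean total n: %.1f\n",
              x$pct_nds, x$mean_total_n))
  invisible(x)
}
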