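#' Trial design configuration
#'
#' Collects the operational parameters of a cohort-based phase I-II trial:
#' cohort size, maximum sample size, starting dose, the utility stack that
#' drives dose selection, and the active admissibility/stopping rule.
#'
#' Three rule variants are supported:
#' * `"conventional_admissibility"`: a dose is admissible when
#'   `Pr(pi_E > adm_eff[1] | y) > adm_eff[2]` and
#'   `Pr(pi_T < adm_tox[1] | y) > adm_tox[2]` — small evidence floors that
#'   exclude a dose only once the data speak clearly against it.  The trial
#'   stops with no dose selected when no dose is admissible.
#' * `"utility_admissibility"`: a single rule on the utility scale.  A dose
#'   is excluded when `Pr(u < u_ref | y) > 1 - pu`, where `u_ref` is the
#'   joint utility at the elicited contour point
#'   `(contour_eff, contour_tox)`.  The trial stops when all doses are
#'   excluded.
#' * `"utility_trial_stop"`: the same criterion is used only to stop the
#'   whole trial; while it runs, the expected-utility argmax is taken over
#'   all doses.
#'
#' @param utility A [utility_stack()].
#' @param rule_variant One of the three rule variants above.
#' @param cohort_size Patients per cohort (default 3).
#' @param max_n Maximum sample size (default 45; must be a multiple of the
#'   cohort size).
#' @param start_dose_index Dose for the first cohort (default 1, the
#'   lowest).
#' @param adm_eff,adm_tox Length-2 vectors `(threshold, evidence floor)`
#'   for the conventional rules.
#' @param contour_eff,contour_tox Elicited contour point for the utility
#'   rules; its joint utility becomes the reference `u_ref`.
#' @param pu Stopping-rule threshold in (0, 1) (default 0.1): doses are
#'   unacceptable when the posterior probability of lying below the contour
#'   exceeds `1 - pu`.
#' @param label Optional design label.
#' @return An object of class `r2dt_design`.
#' @seealso [design_preset()] for the ready-made design variants.
#' @export
design_config <- function(utility,
                          rule_variant = c("conventional_admissibility",
                                           "utility_admissibility",
                                           "utility_trial_stop"),
                          cohort_size = 3L, max_n = 45L,
                          start_dose_index = 1L,
                          adm_eff = c(0.5, 0.075), adm_tox = c(0.4, 0.075),
                          contour_eff = NULL, contour_tox = NULL,
                          pu = 0.1, label = NULL) {
  rule_variant <- match.arg(rule_variant)
  stopifnot(inherits(utility, "r2dt_utility"))
  if (cohort_size < 1 || max_n < cohort_size || max_n %% cohort_size != 0)
    stop("`max_n` must be a positive multiple of `cohort_size`",
         call. = FALSE)
  if (pu <= 0 || pu >= 1) stop("`pu` must lie in (0, 1)", call. = FALSE)
  u_ref <- NULL
  if (rule_variant == "conventional_admissibility") {
    for (a in list(adm_eff, adm_tox))
      if (length(a) != 2L || a[1] <= 0 || a[1] >= 1 || a[2] <= 0 || a[2] >= 1)
        stop("admissibility parameters must be (threshold, floor) in (0, 1)",
             call. = FALSE)
  } else {
    if (is.null(contour_eff) || is.null(contour_tox))
      stop("utility rules need the contour point (`contour_eff`, ",
           "`contour_tox`)", call. = FALSE)
    u_ref <- stopping_contour_reference(c(contour_eff, contour_tox), utility)
  }
  structure(list(utility = utility, rule_variant = rule_variant,
                 cohort_size = as.integer(cohort_size),
                 max_n = as.integer(max_n),
                 start_dose_index = as.integer(start_dose_index),
                 adm_eff = adm_eff, adm_tox = adm_tox,
                 contour_eff = contour_eff, contour_tox = contour_tox,
                 pu = pu, u_ref = u_ref, label = label),
            class = "r2dt_design")
}

#' @export
print.r2dt_design <- function(x, ...) {
  cat(sprintf("<design%s> cohorts of %d up to n = %d, start dose %d, rule %s\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$cohort_size, x$max_n, x$start_dose_index, x$rule_variant))
  if (!is.null(x$u_ref))
    cat(sprintf("  contour u(%.2f, %.2f) = %.4f, pu = %.2f\n",
                x$contour_eff, x$contour_tox, x$u_ref, x$pu))
  invisible(x)
}

#' Conventional admissibility rule
#'
#' A dose is admissible when there is at least a minimal amount of
#' posterior evidence of sufficient efficacy and acceptable toxicity:
#' `Pr(pi_E > threshold_E) > floor_E` and `Pr(pi_T < threshold_T) >
#' floor_T`.  The floors are deliberately small so that doses are only
#' excluded once the posterior is confidently against them.
#'
#' @param tail_probs A data frame from [posterior_tail_probs()] with
#'   columns `pr_eff_above` and `pr_tox_below`.
#' @param config A [design_config()].
#' @return Logical vector of admissibility flags, one per row.
#' @export
conventional_admissible <- function(tail_probs, config) {
  stopifnot(inherits(config, "r2dt_design"))
  tail_probs$pr_eff_above > config$adm_eff[2] &
    tail_probs$pr_tox_below > config$adm_tox[2]
}

#' Utility-contour admissibility rule
#'
#' A dose is excluded when the posterior probability that its joint
#' utility falls below the reference contour utility exceeds `1 - pu`.
#'
#' @param pr_utility_below Per-dose posterior probabilities
#'   `Pr(u < u_ref | y)`.
#' @param config A [design_config()] with a utility rule variant.
#' @return Logical vector of admissibility flags.
#' @export
utility_admissible <- function(pr_utility_below, config) {
  stopifnot(inherits(config, "r2dt_design"))
  !(pr_utility_below > 1 - config$pu)
}

#' Interim dose decision
#'
#' Applies the Bayes action with the active rule variant: among the doses
#' the rule admits, pick the maximiser of posterior expected utility; then
#' cap escalation at one level above the highest dose already assessed (the
#' no-skip rule).  Under `"utility_trial_stop"` the argmax runs over all
#' doses and the trial stops only when every dose violates the stopping
#' criterion.  Ties are broken towards the lowest dose index.
#'
#' @param expected_utilities Per-dose posterior expected utilities.
#' @param admissible Logical per-dose admissibility flags (from the rule
#'   matching `config$rule_variant`).
#' @param highest_tried Highest dose index already assessed.
#' @param config A [design_config()].
#' @return A list of class `r2dt_decision`: `action`
#'   (`"treat_at_dose"`/`"stop_no_dose"`), `dose_index`,
#'   `expected_utilities`, `admissible`.
#' @export
select_dose <- function(expected_utilities, admissible, highest_tried,
                        config) {
  stopifnot(inherits(config, "r2dt_design"),
            length(expected_utilities) == length(admissible))
  if (!any(admissible)) {
    return(structure(list(action = "stop_no_dose", dose_index = NA_integer_,
                          expected_utilities = expected_utilities,
                          admissible = admissible),
                     class = "r2dt_decision"))
  }
  pool <- if (config$rule_variant == "utility_trial_stop")
    seq_along(expected_utilities) else which(admissible)
  best <- pool[which.max(expected_utilities[pool])]  # lowest index on ties
  if (best > highest_tried + 1L) best <- highest_tried + 1L
  structure(list(action = "treat_at_dose", dose_index = as.integer(best),
                 expected_utilities = expected_utilities,
                 admissible = admissible),
            class = "r2dt_decision")
}

#' Final dose selection
#'
#' The decision after the final cohort uses the same rule set as the
#' interims but without the no-skip cap, since no further patients are
#' treated.  An empty admissible set maps to no dose selected (NDS).
#'
#' @inheritParams select_dose
#' @return An `r2dt_decision`; `action == "stop_no_dose"` means NDS.
#' @export
final_selection <- function(expected_utilities, admissible, config) {
  stopifnot(inherits(config, "r2dt_design"))
  if (!any(admissible)) {
    return(structure(list(action = "stop_no_dose", dose_index = NA_integer_,
                          expected_utilities = expected_utilities,
                          admissible = admissible),
                     class = "r2dt_decision"))
  }
  pool <- if (config$rule_variant == "utility_trial_stop")
    seq_along(expected_utilities) else which(admissible)
  best <- pool[which.max(expected_utilities[pool])]
  structure(list(action = "treat_at_dose", dose_index = as.integer(best),
                 expected_utilities = expected_utilities,
                 admissible = admissible),
            class = "r2dt_decision")
}

#' @export
print.r2dt_decision <- function(x, ...) {
  if (x$action == "stop_no_dose") cat("<decision> stop, no dose selected\n")
  else cat(sprintf("<decision> treat at dose %d (E[u] = %.3f)\n",
                   x$dose_index, x$expected_utilities[x$dose_index]))
  invisible(x)
}

# admissibility flags for the active rule variant, from posterior draws
.admissibility_flags <- function(draws, grid, config) {
  if (config$rule_variant == "conventional_admissibility") {
    tp <- posterior_tail_probs(draws, grid,
                               eff_above = config$adm_eff[1],
                               tox_below = config$adm_tox[1])
    conventional_admissible(tp, config)
  } else {
    tp <- posterior_tail_probs(draws, grid, u_ref = config$u_ref,
                               utility = config$utility)
    utility_admissible(tp$pr_utility_below, config)
  }
}
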