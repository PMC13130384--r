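#' Built-in simulation scenarios
#'
#' Ten fixed dose-response scenarios for the four-dose (20/30/40/50 mg/kg)
#' setting: true efficacy and toxicity probability vectors together with
#' the tabulated optimal action (a dose index, or `NA` when no dose should
#' be selected because every dose breaches the acceptability bounds).
#' They span steep and flat efficacy curves, benign and steeply toxic dose
#' ranges, an efficacy plateau, and two scenarios where the correct answer
#' is to stop without selecting a dose.
#'
#' @return A named list of `r2dt_scenario` objects, each with fields
#'   `name`, `true_eff`, `true_tox` and `optimal_dose`.
#' @export
builtin_scenarios <- function() {
  mk <- function(name, eff, tox, optimal) {
    structure(list(name = name, true_eff = eff, true_tox = tox,
                   optimal_dose = optimal),
              class = "r2dt_scenario")
  }
  list(
    scenario1 = mk("scenario1", c(0.30, 0.57, 0.75, 0.85),
                   c(0.05, 0.08, 0.12, 0.15), 4L),
    scenario2 = mk("scenario2", c(0.37, 0.45, 0.51, 0.55),
                   c(0.05, 0.08, 0.12, 0.15), 4L),
    scenario3 = mk("scenario3", c(0.30, 0.57, 0.75, 0.85),
                   c(0.05, 0.13, 0.23, 0.35), 3L),
    scenario4 = mk("scenario4", c(0.37, 0.45, 0.51, 0.55),
                   c(0.05, 0.13, 0.23, 0.35), 3L),
    scenario5 = mk("scenario5", c(0.55, 0.75, 0.85, 0.90),
                   c(0.35, 0.42, 0.47, 0.51), 1L),
    scenario6 = mk("scenario6", c(0.60, 0.62, 0.63, 0.64),
                   c(0.26, 0.35, 0.42, 0.48), 1L),
    scenario7 = mk("scenario7", c(0.26, 0.60, 0.70, 0.70),
                   c(0.05, 0.13, 0.23, 0.35), 3L),
    scenario8 = mk("scenario8", c(0.26, 0.60, 0.70, 0.70),
                   c(0.18, 0.35, 0.50, 0.62), 2L),
    scenario9 = mk("scenario9", c(0.55, 0.75, 0.85, 0.90),
                   c(0.45, 0.57, 0.64, 0.70), NA_integer_),
    scenario10 = mk("scenario10", c(0.20, 0.30, 0.38, 0.45),
                    c(0.05, 0.08, 0.12, 0.15), NA_integer_))
}

#' @export
print.r2dt_scenario <- function(x, ...) {
  cat(sprintf("<scenario %s>\n", x$name))
  print(rbind(p_eff = x$true_eff, p_tox = x$true_tox))
  cat("optimal dose:",
      if (is.na(x$optimal_dose)) "none (NDS)" else x$optimal_dose, "\n")
  invisible(x)
}

#' Optimal dose under a utility stack, given the true probabilities
#'
#' Defines the benchmark answer for a scenario: doses with true toxicity
#' above `tox_bound` or true efficacy below `eff_bound` cannot be optimal;
#' among the remainder the dose with the highest joint utility at the true
#' probabilities is optimal.  When every dose is excluded the correct
#' action is to select no dose.
#'
#' @param scenario A scenario from [builtin_scenarios()] (or any list with
#'   `true_eff`/`true_tox`).
#' @param utility A [utility_stack()].
#' @param eff_bound,tox_bound Acceptability bounds (defaults 0.5 and 0.4).
#' @return A dose index, or `NA_integer_` when no dose is acceptable.
#' @export
optimal_dose_oracle <- function(scenario, utility,
                                eff_bound = 0.5, tox_bound = 0.4) {
  ok <- scenario$true_eff >= eff_bound & scenario$true_tox <= tox_bound
  if (!any(ok)) return(NA_integer_)
  u <- evaluate_utility(utility, scenario$true_eff, scenario$true_tox)
  which(ok)[which.max(u[ok])]
}
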