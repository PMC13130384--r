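#' Ready-made utility stacks
#'
#' Returns the utility parameterisations used throughout the package's
#' worked examples and simulations:
#' * `"R2DT1"` — reference-dependent marginals (efficacy reference 0.5,
#'   toxicity reference 0.35, loss aversion 2, all risk exponents 0.7) with
#'   corner weights `kE = 0.25`, `kT = 0.15` (sigmoidal / inverted
#'   sigmoidal marginals).
#' * `"EffToxU"` — the degenerate linear-marginal case with the same corner
#'   weights (patient-outcome utilities 0.25 and 0.15).
#' * `"EffToxU7"` — linear marginals with the larger corner weights
#'   `kE = 0.5`, `kT = 0.3` (same ratio, weaker interaction).
#'
#' @param name Preset name.
#' @return A [utility_stack()].
#' @export
utility_preset <- function(name = c("R2DT1", "EffToxU", "EffToxU7")) {
  name <- match.arg(name)
  linear <- function() list(
    eff = marginal_utility_spec(0.5, 1, 1, 1, "efficacy"),
    tox = marginal_utility_spec(0.35, 1, 1, 1, "toxicity"))
  switch(name,
    R2DT1 = utility_stack(
      marginal_utility_spec(0.5, 2, 0.7, 0.7, "efficacy"),
      marginal_utility_spec(0.35, 2, 0.7, 0.7, "toxicity"),
      joint_utility_spec(0.25, 0.15)),
    EffToxU = {
      m <- linear()
      utility_stack(m$eff, m$tox, joint_utility_spec(0.25, 0.15))
    },
    EffToxU7 = {
      m <- linear()
      utility_stack(m$eff, m$tox, joint_utility_spec(0.5, 0.3))
    })
}

#' Ready-made design variants
#'
#' Expands a design label into a full [design_config()] on the four-dose
#' grid with cohorts of 3 up to 45 patients, starting at the lowest dose:
#'
#' | label | utility | rule |
#' |-------|---------|------|
#' | `R2DT1`    | reference-dependent | conventional admissibility |
#' | `EffToxU2` | linear marginals    | conventional admissibility |
#' | `R2DT3i`/`R2DT3ii`/`R2DT3iii` | reference-dependent | utility admissibility at contour (0.5, 0.35) / (0.7, 0.4) / (0.9, 0.4) |
#' | `R2DT4i`/`R2DT4ii`/`R2DT4iii` | reference-dependent | utility trial-stop at the same contours |
#' | `EffToxU5` | linear marginals | utility admissibility at contour (0.5, 0.35) |
#' | `EffToxU7` | linear, `kE = 0.5`, `kT = 0.3` | conventional admissibility |
#'
#' Conventional admissibility uses thresholds 0.5 (efficacy) and 0.4
#' (toxicity) with evidence floors 0.075; the utility rules use
#' `pu = 0.1`.
#'
#' @param name Design label.
#' @return A [design_config()].
#' @export
design_preset <- function(name = c("R2DT1", "EffToxU2", "R2DT3i", "R2DT3ii",
                                   "R2DT3iii", "R2DT4i", "R2DT4ii",
                                   "R2DT4iii", "EffToxU5", "EffToxU7")) {
  name <- match.arg(name)
  contours <- list(i = c(0.5, 0.35), ii = c(0.7, 0.4), iii = c(0.9, 0.4))
  if (name %in% c("R2DT1", "EffToxU2", "EffToxU7")) {
    u <- utility_preset(switch(name, R2DT1 = "R2DT1", EffToxU2 = "EffToxU",
                               EffToxU7 = "EffToxU7"))
    return(design_config(u, "conventional_admissibility", label = name))
  }
  if (name == "EffToxU5") {
    return(design_config(utility_preset("EffToxU"), "utility_admissibility",
                         contour_eff = 0.5, contour_tox = 0.35,
                         label = name))
  }
  roman <- sub("^R2DT[34]", "", name)
  variant <- if (grepl("^R2DT3", name)) "utility_admissibility"
             else "utility_trial_stop"
  pt <- contours[[roman]]
  design_config(utility_preset("R2DT1"), variant,
                contour_eff = pt[1], contour_tox = pt[2], label = name)
}
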