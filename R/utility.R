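#' Reference-dependent marginal utility specification
#'
#' Defines a piecewise power utility for a single attribute (the probability
#' of an efficacy event or of a toxicity event).  Outcomes are framed as
#' gains or losses relative to a clinical reference point: for efficacy the
#' reference is typically the response rate of the standard of care, for
#' toxicity the target toxicity level.  On each side of the reference a
#' power function with its own exponent describes the attitude to risk, and
#' losses are weighted by a loss-aversion index.
#'
#' The unnormalised utility of a probability `p` is
#' \deqn{v(t) = t^{\alpha_G} \text{ for } t \ge 0, \qquad
#'       v(t) = -\lambda (-t)^{\alpha_L} \text{ for } t < 0,}
#' where `t = p - reference` for efficacy and `t = reference - p` for
#' toxicity (so that more toxicity is always worse).  The returned utility is
#' rescaled affinely so that the worst attainable outcome (no efficacy,
#' resp. certain toxicity) has utility 0 and the best has utility 1.
#'
#' @param reference Reference probability strictly inside (0, 1).
#' @param loss_aversion Loss-aversion index \eqn{\lambda \ge 0}.  Values
#'   above 1 weight losses more heavily than equal-sized gains; 0 collapses
#'   the loss branch to the reference value and triggers a warning.
#' @param exp_gain,exp_loss Risk exponents for the gain and loss branches,
#'   strictly positive.  1 is risk neutrality; the zero-exponent step
#'   function limit is not representable and is rejected.
#' @param orientation `"efficacy"` (utility nondecreasing in `p`) or
#'   `"toxicity"` (nonincreasing).
#' @return An object of class `r2dt_marginal`.
#' @examples
#' eff <- marginal_utility_spec(0.5, 2, 0.7, 0.7, "efficacy")
#' marginal_utility(eff, c(0, 0.5, 1))
#' @export
marginal_utility_spec <- function(reference, loss_aversion, exp_gain,
                                  exp_loss, orientation = c("efficacy",
                                                            "toxicity")) {
  orientation <- match.arg(orientation)
  if (!is.numeric(reference) || length(reference) != 1L ||
      reference <= 0 || reference >= 1)
    stop("`reference` must be a single probability strictly inside (0, 1)",
         call. = FALSE)
  if (!is.numeric(loss_aversion) || length(loss_aversion) != 1L ||
      loss_aversion < 0)
    stop("`loss_aversion` must be a single nonnegative number",
         call. = FALSE)
  if (loss_aversion == 0)
    warning("loss_aversion = 0 flattens the loss branch; ",
            "values above 1 are recommended", call. = FALSE)
  for (e in c(gain = exp_gain, loss = exp_loss)) {
    if (!is.numeric(e) || length(e) != 1L || !is.finite(e) || e <= 0)
      stop("risk exponents must be strictly positive; the step-function ",
           "limit at 0 is not representable", call. = FALSE)
  }
  spec <- structure(
    list(reference = reference, loss_aversion = loss_aversion,
         exp_gain = exp_gain, exp_loss = exp_loss,
         orientation = orientation),
    class = "r2dt_marginal")
  # range of the unnormalised utility; must be positive for the rescaling
  lo <- .raw_marginal(spec, if (orientation == "efficacy") 0 else 1)
  hi <- .raw_marginal(spec, if (orientation == "efficacy") 1 else 0)
  if (!(hi - lo > 0))
    stop("degenerate specification: normaliser denominator is not positive",
         call. = FALSE)
  spec$raw_lo <- lo
  spec$raw_hi <- hi
  spec
}

# unnormalised piecewise power utility on the gain/loss transform
.raw_marginal <- function(spec, p) {
  t <- if (spec$orientation == "efficacy") p - spec$reference
       else spec$reference - p
  gain <- t >= 0
  v <- numeric(length(t))
  v[gain] <- t[gain]^spec$exp_gain
  v[!gain] <- -spec$loss_aversion * (-t[!gain])^spec$exp_loss
  v
}

#' Evaluate a marginal utility
#'
#' @param spec An [marginal_utility_spec()] object.
#' @param p Vector of probabilities in \[0, 1\].
#' @return Utilities in \[0, 1\]; 0 and 1 at the worst and best attainable
#'   outcome respectively.
#' @export
marginal_utility <- function(spec, p) {
  stopifnot(inherits(spec, "r2dt_marginal"))
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("`p` must be probabilities in [0, 1]", call. = FALSE)
  (.raw_marginal(spec, p) - spec$raw_lo) / (spec$raw_hi - spec$raw_lo)
}

#' @export
print.r2dt_marginal <- function(x, ...) {
  cat(sprintf(
    "<%s marginal utility> reference %.3g, loss aversion %.3g, exponents (gain %.3g, loss %.3g)\n",
    x$orientation, x$reference, x$loss_aversion, x$exp_gain, x$exp_loss))
  invisible(x)
}

#' Joint utility corner weights
#'
#' The joint utility of an (efficacy, toxicity) probability pair combines
#' the two marginal utilities multiplicatively,
#' \deqn{u(\pi_E, \pi_T) = k_E u_E + k_T u_T + k_{ET} u_E u_T,}
#' with \eqn{k_{ET} = 1 - k_E - k_T}.  `k_eff` is the utility of the outcome
#' where both efficacy and toxicity are certain (\eqn{u_E = 1, u_T = 0}) and
#' `k_tox` the utility where neither occurs (\eqn{u_E = 0, u_T = 1}).  A sum
#' below 1 gives a positive interaction between the attributes.
#'
#' @param k_eff,k_tox Corner weights in \[0, 1\].
#' @return An object of class `r2dt_joint` with the derived interaction
#'   weight `k_int`.
#' @export
joint_utility_spec <- function(k_eff, k_tox) {
  for (k in c(k_eff, k_tox))
    if (!is.numeric(k) || length(k) != 1L || k < 0 || k > 1)
      stop("corner weights must be single numbers in [0, 1]", call. = FALSE)
  structure(list(k_eff = k_eff, k_tox = k_tox,
                 k_int = 1 - k_eff - k_tox),
            class = "r2dt_joint")
}

#' @export
print.r2dt_joint <- function(x, ...) {
  cat(sprintf("<joint utility> kE = %.3g, kT = %.3g, kET = %.3g\n",
              x$k_eff, x$k_tox, x$k_int))
  invisible(x)
}

#' Combine marginal utilities into a joint utility
#'
#' @param jspec A [joint_utility_spec()].
#' @param u_eff,u_tox Marginal utilities in \[0, 1\] (vectors recycle).
#' @return Joint utilities in \[0, 1\].
#' @export
joint_utility <- function(jspec, u_eff, u_tox) {
  stopifnot(inherits(jspec, "r2dt_joint"))
  if (any(u_eff < -1e-12 | u_eff > 1 + 1e-12) ||
      any(u_tox < -1e-12 | u_tox > 1 + 1e-12))
    stop("marginal utilities must lie in [0, 1]", call. = FALSE)
  jspec$k_eff * u_eff + jspec$k_tox * u_tox + jspec$k_int * u_eff * u_tox
}

#' Full reference-dependent utility stack
#'
#' Bundles the efficacy marginal, toxicity marginal and corner weights into
#' one object that maps an (efficacy, toxicity) probability pair to a joint
#' utility.
#'
#' @param eff,tox [marginal_utility_spec()] objects with efficacy and
#'   toxicity orientation respectively.
#' @param joint A [joint_utility_spec()].
#' @return An object of class `r2dt_utility`.
#' @seealso [utility_preset()] for the parameter sets used in the package's
#'   worked examples.
#' @export
utility_stack <- function(eff, tox, joint) {
  stopifnot(inherits(eff, "r2dt_marginal"), inherits(tox, "r2dt_marginal"),
            inherits(joint, "r2dt_joint"))
  if (eff$orientation != "efficacy" || tox$orientation != "toxicity")
    stop("`eff` must have efficacy orientation and `tox` toxicity ",
         "orientation", call. = FALSE)
  structure(list(eff = eff, tox = tox, joint = joint),
            class = "r2dt_utility")
}

#' @export
print.r2dt_utility <- function(x, ...) {
  print(x$eff); print(x$tox); print(x$joint)
  invisible(x)
}

#' Evaluate the joint utility of probability pairs
#'
#' @param stack A [utility_stack()].
#' @param p_eff,p_tox Probabilities of efficacy and toxicity (vectors
#'   recycle).
#' @return Joint utilities in \[0, 1\].
#' @examples
#' u <- utility_preset("R2DT1")
#' evaluate_utility(u, 0.5, 0.35)  # 0.582: the reference-point utility
#' @export
evaluate_utility <- function(stack, p_eff, p_tox) {
  stopifnot(inherits(stack, "r2dt_utility"))
  joint_utility(stack$joint,
                marginal_utility(stack$eff, p_eff),
                marginal_utility(stack$tox, p_tox))
}

#' Linear patient-outcome utility (EffToxU)
#'
#' The established numerical-utility alternative assigns utility `k11` to a
#' patient experiencing both efficacy and toxicity and `k00` to one
#' experiencing neither (with 1 for efficacy alone and 0 for toxicity
#' alone).  Under an independence probability model its expected value is a
#' degenerate case of the reference-dependent joint utility with linear
#' marginals \eqn{u_E = \pi_E} and \eqn{u_T = 1 - \pi_T}:
#' \deqn{u(\pi_E, \pi_T) = k_{11} \pi_E + k_{00} (1 - \pi_T)
#'       + (1 - k_{11} - k_{00})\, \pi_E (1 - \pi_T).}
#'
#' @param k11,k00 Patient-outcome utilities in \[0, 1\].
#' @param p_eff,p_tox Probabilities of efficacy and toxicity.
#' @return Utilities in \[0, 1\].
#' @examples
#' efftoxu_utility(0.25, 0.15, 0.5, 0.35)  # 0.4175
#' @export
efftoxu_utility <- function(k11, k00, p_eff, p_tox) {
  for (k in c(k11, k00))
    if (!is.numeric(k) || k < 0 || k > 1)
      stop("`k11` and `k00` must lie in [0, 1]", call. = FALSE)
  if (any(p_eff < 0 | p_eff > 1) || any(p_tox < 0 | p_tox > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  k11 * p_eff + k00 * (1 - p_tox) + (1 - k11 - k00) * p_eff * (1 - p_tox)
}
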