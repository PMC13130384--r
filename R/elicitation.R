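#' Certainty equivalent of a simple lottery
#'
#' Given a marginal utility and a lottery paying attribute level `x1` with
#' probability `mix_w` and `x3` otherwise, returns the sure level `x2` the
#' decision maker should be indifferent to:
#' `u(x2) = mix_w u(x1) + (1 - mix_w) u(x3)`.  The inversion uses the
#' monotonicity of the marginal utility on \[0, 1\].
#'
#' @param spec A [marginal_utility_spec()].
#' @param x1,x3 Attribute levels (probabilities) in \[0, 1\].
#' @param mix_w Probability weight on `x1`, in (0, 1).
#' @return The certainty equivalent in \[0, 1\].
#' @examples
#' neutral <- marginal_utility_spec(0.5, 1, 1, 1, "efficacy")
#' certainty_equivalent(neutral, 0.5, 1.0)  # risk neutrality: 0.75
#' @export
certainty_equivalent <- function(spec, x1, x3, mix_w = 0.5) {
  stopifnot(inherits(spec, "r2dt_marginal"))
  if (any(c(x1, x3) < 0 | c(x1, x3) > 1))
    stop("lottery levels must lie in [0, 1]", call. = FALSE)
  if (mix_w <= 0 || mix_w >= 1)
    stop("`mix_w` must lie in (0, 1)", call. = FALSE)
  if (x1 == x3) return(x1)
  target <- mix_w * marginal_utility(spec, x1) +
    (1 - mix_w) * marginal_utility(spec, x3)
  f <- function(x) marginal_utility(spec, x) - target
  if (abs(f(0)) < 1e-14) return(0)
  if (abs(f(1)) < 1e-14) return(1)
  stats::uniroot(f, c(0, 1), tol = 1e-12)$root
}

#' Solve a risk exponent from a stated indifference point
#'
#' For a lottery with both levels strictly on one side of the reference
#' point, the indifference relation depends only on the power exponent of
#' that branch (affine renormalisation and the loss-aversion factor cancel).
#' The exponent solving
#' `mix_w a1^alpha + (1 - mix_w) a3^alpha = a2^alpha` (with `a` the
#' absolute distances from the reference) is found by bracketed root search
#' on the log-exponent in `[log 1e-3, log 1e3]`.
#'
#' @param x1,x3 Lottery levels, strictly on one side of `reference`.
#' @param indiff Stated certainty equivalent, strictly between the lottery
#'   levels.
#' @param reference The reference point of the marginal utility.
#' @param orientation `"efficacy"` or `"toxicity"` (fixes the gain/loss
#'   direction of the transform).
#' @param mix_w Probability weight on `x1`.
#' @return The recovered exponent in (0.001, 1000).  An indifference point
#'   equal to the risk-neutral expectation (within 1e-10) returns exactly 1.
#' @export
solve_risk_exponent <- function(x1, x3, indiff, reference,
                                orientation = c("efficacy", "toxicity"),
                                mix_w = 0.5) {
  orientation <- match.arg(orientation)
  tf <- function(x) if (orientation == "efficacy") x - reference
                    else reference - x
  t1 <- tf(x1); t3 <- tf(x3); t2 <- tf(indiff)
  if (sign(t1) * sign(t3) < 0 || (t1 == 0 && t3 == 0))
    stop("both lottery levels must lie on one side of the reference ",
         "(one may sit at the reference itself)", call. = FALSE)
  side <- sign(t1 + t3)
  if (sign(t2) != side)
    stop("the indifference point must lie on the same side of the ",
         "reference as the lottery", call. = FALSE)
  a1 <- abs(t1); a3 <- abs(t3); a2 <- abs(t2)
  if (a2 <= min(a1, a3) || a2 >= max(a1, a3))
    stop("elicitation inconsistency: the indifference point must lie ",
         "strictly between the lottery levels", call. = FALSE)
  if (abs(mix_w * a1 + (1 - mix_w) * a3 - a2) < 1e-10) return(1)
  if (a1 == 0 || a3 == 0) {
    # one level at the reference: the indifference relation reduces to
    # (a2 / a)^alpha = weight on the nonzero level, solved in closed form
    a <- max(a1, a3)
    w <- if (a1 == 0) 1 - mix_w else mix_w
    alpha <- log(w) / log(a2 / a)
    if (alpha < 1e-3 || alpha > 1e3)
      stop("elicitation inconsistency: no exponent in (0.001, 1000) ",
           "matches the stated indifference", call. = FALSE)
    return(alpha)
  }
  # the certainty equivalent on one power branch is the weighted power
  # mean of the distances; its log is monotone increasing in the
  # exponent, giving a guaranteed bracket (evaluated via log-sum-exp for
  # numerical range)
  l1 <- log(a1); l3 <- log(a3); l2 <- log(a2)
  f <- function(loga) {
    al <- exp(loga)
    m <- max(al * l1, al * l3)
    lse <- m + log(mix_w * exp(al * l1 - m) +
                   (1 - mix_w) * exp(al * l3 - m))
    lse / al - l2
  }
  lo <- log(1e-3); hi <- log(1e3)
  if (f(lo) * f(hi) > 0)
    stop("elicitation inconsistency: no exponent in (0.001, 1000) matches ",
         "the stated indifference", call. = FALSE)
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
}

#' Solve the loss-aversion index from a reference-spanning lottery
#'
#' With the two risk exponents already elicited, a lottery whose levels
#' straddle the reference pins down the loss-aversion index.  Because the
#' index enters the unnormalised utility linearly, the solution is in
#' closed form.
#'
#' @param x1,x3 Lottery levels on opposite sides of the reference (in
#'   transformed terms: `x1` on the loss side, `x3` on the gain side).
#' @param indiff Stated certainty equivalent.
#' @param exp_gain,exp_loss The previously solved risk exponents.
#' @inheritParams solve_risk_exponent
#' @return The loss-aversion index (nonnegative).
#' @export
solve_loss_aversion <- function(x1, x3, indiff, reference,
                                exp_gain, exp_loss,
                                orientation = c("efficacy", "toxicity"),
                                mix_w = 0.5) {
  orientation <- match.arg(orientation)
  tf <- function(x) if (orientation == "efficacy") x - reference
                    else reference - x
  t1 <- tf(x1); t3 <- tf(x3); t2 <- tf(indiff)
  if (!(t1 < 0 && t3 > 0))
    stop("the lottery must span the reference (one loss, one gain level)",
         call. = FALSE)
  A <- (-t1)^exp_loss       # loss-side distance term (weighted by lambda)
  G <- t3^exp_gain          # gain-side term
  lambda <- if (t2 >= 0) {
    ((1 - mix_w) * G - t2^exp_gain) / (mix_w * A)
  } else {
    (1 - mix_w) * G / (mix_w * A - (-t2)^exp_loss)
  }
  if (!is.finite(lambda) || lambda < 0)
    stop("elicitation inconsistency: stated indifference implies a ",
         "negative loss-aversion index", call. = FALSE)
  lambda
}

#' Solve the joint-utility corner weights from stated equivalences
#'
#' Each statement pins one linear equation in `(kE, kT)` after substituting
#' `kET = 1 - kE - kT`.  Two forms are accepted:
#' * `list(points = list(c(pE1, pT1), c(pE2, pT2)))` — the two outcome
#'   points are judged equally desirable;
#' * `list(point = c(pE, pT), utility = v)` — the point is assigned the
#'   stated utility directly (the corner statements "utility of efficacy
#'   with toxicity" / "utility of neither" are the special cases
#'   `point = c(1, 1)` and `c(0, 0)`).
#'
#' @param equivalences List of two statements in the forms above.
#' @param eff,tox The already-elicited marginal utilities
#'   ([marginal_utility_spec()]).
#' @return A [joint_utility_spec()]; a warning is issued when
#'   `kE + kT >= 1` (no positive interaction).
#' @export
solve_joint_weights <- function(equivalences, eff, tox) {
  if (length(equivalences) != 2L)
    stop("exactly two equivalence statements are required", call. = FALSE)
  row_of <- function(eq, i) {
    if (!is.null(eq$points)) {
      u1 <- c(marginal_utility(eff, eq$points[[1]][1]),
              marginal_utility(tox, eq$points[[1]][2]))
      u2 <- c(marginal_utility(eff, eq$points[[2]][1]),
              marginal_utility(tox, eq$points[[2]][2]))
      det <- u1[1] * u1[2] - u2[1] * u2[2]
      c(u1[1] - u2[1] - det, u1[2] - u2[2] - det, -det)
    } else if (!is.null(eq$point)) {
      uE <- marginal_utility(eff, eq$point[1])
      uT <- marginal_utility(tox, eq$point[2])
      c(uE - uE * uT, uT - uE * uT, eq$utility - uE * uT)
    } else {
      stop(sprintf("equivalence %d has neither `points` nor `point`", i),
           call. = FALSE)
    }
  }
  rows <- rbind(row_of(equivalences[[1]], 1), row_of(equivalences[[2]], 2))
  A <- rows[, 1:2, drop = FALSE]
  if (abs(det(A)) < 1e-10)
    stop("the two equivalences are colinear and do not identify the ",
         "corner weights", call. = FALSE)
  k <- solve(A, rows[, 3])
  if (any(k < -1e-9) || any(k > 1 + 1e-9))
    stop("solved corner weights fall outside [0, 1]; revise the ",
         "equivalences", call. = FALSE)
  k <- pmin(pmax(k, 0), 1)
  if (sum(k) >= 1)
    warning("kE + kT >= 1: no positive interaction between attributes",
            call. = FALSE)
  joint_utility_spec(k[1], k[2])
}

#' Reference utility from a stopping-contour point
#'
#' The stopping rule needs a single elicited point `(x, y)` on the contour
#' of minimally acceptable (efficacy, toxicity) combinations; the joint
#' utility at that point is the reference utility `u_ref` against which
#' posterior utilities are compared.
#'
#' @param point Length-2 vector `(p_eff, p_tox)` with both entries in
#'   (0, 1).
#' @param stack A [utility_stack()].
#' @return The reference utility in \[0, 1\].
#' @examples
#' stopping_contour_reference(c(0.7, 0.4), utility_preset("R2DT1"))  # 0.623
#' @export
stopping_contour_reference <- function(point, stack) {
  if (length(point) != 2L || any(point <= 0) || any(point >= 1))
    stop("`point` must be two probabilities strictly inside (0, 1)",
         call. = FALSE)
  evaluate_utility(stack, point[1], point[2])
}

#' Forward consistency check of an elicited utility stack
#'
#' For each extra lottery, compares the stated indifference point with the
#' certainty equivalent implied by the fitted marginal utility and reports
#' the discrepancy.  Reporting only; no error is raised.
#'
#' @param stack A [utility_stack()].
#' @param lotteries Data frame with columns `attribute`
#'   (`"efficacy"`/`"toxicity"`), `x1`, `x3`, `mix_w`, `indiff`.
#' @return The input with extra columns `implied` and `discrepancy`
#'   (`stated - implied`).
#' @export
consistency_check <- function(stack, lotteries) {
  stopifnot(inherits(stack, "r2dt_utility"), is.data.frame(lotteries))
  lotteries$implied <- vapply(seq_len(nrow(lotteries)), function(i) {
    spec <- if (lotteries$attribute[i] == "efficacy") stack$eff else stack$tox
    certainty_equivalent(spec, lotteries$x1[i], lotteries$x3[i],
                         lotteries$mix_w[i])
  }, numeric(1))
  lotteries$discrepancy <- lotteries$indiff - lotteries$implied
  lotteries
}
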