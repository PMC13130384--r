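test_that("certainty equivalents match hand-derived values", {
  neutral <- marginal_utility_spec(0.5, 1, 1, 1, "efficacy")
  # risk neutrality: the certainty equivalent is the lottery expectation
  expect_equal(certainty_equivalent(neutral, 0.5, 1.0), 0.75,
               tolerance = 1e-9)
  expect_equal(certainty_equivalent(neutral, 0.4, 0.6, mix_w = 0.25), 0.55,
               tolerance = 1e-9)
  # concave gains: CE below the expectation; closed-form inversion
  eff <- marginal_utility_spec(0.5, 2, 0.7, 0.7, "efficacy")
  expect_equal(certainty_equivalent(eff, 0.5, 0.7), 0.5742997,
               tolerance = 1e-6)
  # degenerate lottery
  expect_equal(certainty_equivalent(eff, 0.3, 0.3), 0.3)
})

test_that("risk-exponent solver inverts the forward direction", {
  # risk-neutral answer returns exactly 1
  expect_equal(solve_risk_exponent(0.4, 0.6, 0.5, reference = 0.4,
                                   orientation = "efficacy"), 1)
  # inverse of the forward example
  expect_equal(solve_risk_exponent(0.5, 0.7, 0.5742997, reference = 0.5,
                                   orientation = "efficacy"),
               0.7, tolerance = 1e-5)
  # CE below the risk-neutral mean on the gain branch implies aversion
  a <- solve_risk_exponent(0.5, 0.7, 0.57, reference = 0.5,
                           orientation = "efficacy")
  expect_lt(a, 1)
  b <- solve_risk_exponent(0.5, 0.7, 0.63, reference = 0.5,
                           orientation = "efficacy")
  expect_gt(b, 1)
  # inconsistent statements are rejected
  expect_error(solve_risk_exponent(0.5, 0.7, 0.72, reference = 0.5,
                                   orientation = "efficacy"),
               "between the lottery levels")
  expect_error(solve_risk_exponent(0.3, 0.7, 0.5, reference = 0.5,
                                   orientation = "efficacy"),
               "one side")
})

test_that("exponent solution is invariant to relabelling the lottery", {
  set.seed(71)
  for (i in 1:10) {
    ref <- runif(1, 0.2, 0.6)
    x1 <- ref + runif(1, 0.02, 0.1)
    x3 <- x1 + runif(1, 0.05, 0.25)
    w <- runif(1, 0.2, 0.8)
    spec <- marginal_utility_spec(ref, 2, runif(1, 0.3, 2), 0.7, "efficacy")
    ce <- certainty_equivalent(spec, x1, x3, w)
    a1 <- solve_risk_exponent(x1, x3, ce, ref, "efficacy", mix_w = w)
    a2 <- solve_risk_exponent(x3, x1, ce, ref, "efficacy", mix_w = 1 - w)
    expect_equal(a1, a2, tolerance = 1e-7)
    expect_equal(a1, spec$exp_gain, tolerance = 1e-5)
  }
})

test_that("loss-aversion solver has the closed-form special cases", {
  # symmetric lottery, indifference at the reference, equal exponents
  expect_equal(solve_loss_aversion(0.4, 0.6, 0.5, reference = 0.5,
                                   exp_gain = 0.7, exp_loss = 0.7,
                                   orientation = "efficacy"), 1)
  # linear branches with indifference above the risk-neutral point
  lam <- solve_loss_aversion(0.4, 0.6, 0.52, reference = 0.5,
                             exp_gain = 1, exp_loss = 1,
                             orientation = "efficacy")
  expect_lt(lam, 1)
  # negative implied index is an elicitation inconsistency
  expect_error(solve_loss_aversion(0.45, 0.6, 0.62, reference = 0.5,
                                   exp_gain = 1, exp_loss = 1,
                                   orientation = "efficacy"),
               "inconsistency")
})

test_that("loss aversion round-trips through the certainty equivalent", {
  set.seed(81)
  for (orient in c("efficacy", "toxicity")) {
    for (i in 1:10) {
      ref <- runif(1, 0.25, 0.75)
      lam <- runif(1, 0.5, 5)
      aG <- runif(1, 0.3, 2)
      aL <- runif(1, 0.3, 2)
      spec <- marginal_utility_spec(ref, lam, aG, aL, orient)
      x1 <- ref - runif(1, 0.05, min(0.2, ref - 0.02))
      x3 <- ref + runif(1, 0.05, min(0.2, 0.98 - ref))
      if (orient == "toxicity") { tmp <- x1; x1 <- x3; x3 <- tmp }
      ce <- certainty_equivalent(spec, x1, x3)
      got <- solve_loss_aversion(x1, x3, ce, ref, aG, aL, orient)
      expect_equal(got, lam, tolerance = 1e-6)
    }
  }
})

test_that("joint-weight solver recovers stated corners and point pairs", {
  u <- utility_preset("R2DT1")
  # corner statements give the weights directly
  j <- solve_joint_weights(
    list(list(point = c(1, 1), utility = 0.25),
         list(point = c(0, 0), utility = 0.15)),
    u$eff, u$tox)
  expect_equal(j$k_eff, 0.25, tolerance = 1e-12)
  expect_equal(j$k_tox, 0.15, tolerance = 1e-12)
  # round trip through arbitrary interior weights and point equivalences
  set.seed(91)
  for (i in 1:10) {
    kE <- runif(1, 0.1, 0.6)
    kT <- runif(1, 0.05, min(0.9 - kE, 0.4))
    stack <- utility_stack(u$eff, u$tox, joint_utility_spec(kE, kT))
    # build two synthetic equivalences: draw a pair of points and slide
    # one coordinate by root search until both sit on the same utility
    # contour; redraw when the contour does not cross the search segment
    make_eq <- function() {
      repeat {
        m <- matrix(runif(4, 0.05, 0.95), 2, 2)
        target <- evaluate_utility(stack, m[1, 1], m[1, 2])
        f <- function(pt) evaluate_utility(stack, m[2, 1], pt) - target
        g <- function(pe) evaluate_utility(stack, pe, m[2, 2]) - target
        if (f(0.001) * f(0.999) < 0) {
          m[2, 2] <- uniroot(f, c(0.001, 0.999), tol = 1e-12)$root
        } else if (g(0.001) * g(0.999) < 0) {
          m[2, 1] <- uniroot(g, c(0.001, 0.999), tol = 1e-12)$root
        } else next
        # points must differ enough for a well-conditioned system
        if (sum(abs(m[1, ] - m[2, ])) > 0.1) return(
          list(points = list(m[1, ], m[2, ])))
      }
    }
    eq <- list(make_eq(), make_eq())
    j2 <- solve_joint_weights(eq, u$eff, u$tox)
    expect_equal(j2$k_eff, kE, tolerance = 1e-5)
    expect_equal(j2$k_tox, kT, tolerance = 1e-5)
  }
  # duplicated equivalence: singular system
  expect_error(solve_joint_weights(
    list(list(point = c(1, 1), utility = 0.25),
         list(point = c(1, 1), utility = 0.25)),
    u$eff, u$tox), "colinear")
  # weights summing to >= 1 warn about the lost interaction
  expect_warning(solve_joint_weights(
    list(list(point = c(1, 1), utility = 0.7),
         list(point = c(0, 0), utility = 0.5)),
    u$eff, u$tox), "interaction")
})

test_that("stopping-contour reference utilities match the printed values", {
  u <- utility_preset("R2DT1")
  expect_equal(round(stopping_contour_reference(c(0.5, 0.35), u), 2), 0.58)
  expect_equal(round(stopping_contour_reference(c(0.7, 0.40), u), 2), 0.62)
  expect_equal(round(stopping_contour_reference(c(0.9, 0.40), u), 2), 0.69)
  el <- utility_preset("EffToxU")
  expect_equal(round(stopping_contour_reference(c(0.5, 0.35), el), 2), 0.42)
  expect_error(stopping_contour_reference(c(1, 0), u), "strictly inside")
})

test_that("consistency check reports stated-vs-implied discrepancies", {
  u <- utility_preset("R2DT1")
  implied <- certainty_equivalent(u$eff, 0.5, 0.7)
  lot <- data.frame(attribute = c("efficacy", "efficacy", "toxicity"),
                    x1 = c(0.5, 0.5, 0.1), x3 = c(0.7, 0.7, 0.3),
                    mix_w = 0.5,
                    indiff = c(implied, implied + 0.05, 0.2))
  rep <- consistency_check(u, lot)
  expect_equal(rep$discrepancy[1], 0, tolerance = 1e-9)
  expect_equal(rep$discrepancy[2], 0.05, tolerance = 1e-9)
  expect_equal(rep$implied[3],
               certainty_equivalent(u$tox, 0.1, 0.3), tolerance = 1e-9)
})
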