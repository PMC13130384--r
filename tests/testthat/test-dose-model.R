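test_that("centred log-dose transform matches direct arithmetic", {
  g <- dose_grid(c(20, 30, 40, 50))
  expect_equal(g$centered_log[1], -0.5037258, tolerance = 1e-6)
  expect_equal(g$centered_log[4], 0.4125650, tolerance = 1e-6)
  expect_equal(sum(g$centered_log), 0, tolerance = 1e-12)
  # symmetric pair a factor of e apart
  g2 <- dose_grid(c(10, 10 * exp(1)))
  expect_equal(g2$centered_log, c(-0.5, 0.5), tolerance = 1e-12)
  # arbitrary grids centre to zero
  set.seed(11)
  for (i in 1:5) {
    d <- sort(runif(sample(2:8, 1), 1, 100))
    expect_equal(sum(dose_grid(d)$centered_log), 0, tolerance = 1e-10)
  }
  expect_error(dose_grid(c(50, 20)), "increasing")
  expect_error(dose_grid(c(-1, 2)), "positive")
})

test_that("logistic dose-response probabilities behave as specified", {
  th0 <- list(mu_eff = 0, beta_eff1 = 0, beta_eff2 = 0,
              mu_tox = 0, beta_tox = 0)
  expect_equal(prob_efficacy(th0, 0.3), 0.5)
  expect_equal(prob_toxicity(th0, -1), 0.5)
  th <- list(mu_eff = 0, beta_eff1 = 1, beta_eff2 = 0,
             mu_tox = 0, beta_tox = 1)
  expect_equal(prob_efficacy(th, 0.4125650), 0.6017028, tolerance = 1e-6)
  # negative quadratic coefficient gives an interior efficacy maximum
  thq <- list(mu_eff = 0, beta_eff1 = 0.5, beta_eff2 = -2,
              mu_tox = 0, beta_tox = 1)
  fd <- seq(-1, 1, by = 0.01)
  pe <- prob_efficacy(thq, fd)
  vertex <- -0.5 / (2 * -2)  # analytic argmax of the quadratic predictor
  expect_lt(abs(fd[which.max(pe)] - vertex), 0.011)  # grid step is 0.01
  expect_true(which.max(pe) > 1 && which.max(pe) < length(fd))
  # toxicity is monotone in dose; probabilities never hit 0 or 1
  pt <- prob_toxicity(th, fd)
  expect_true(all(diff(pt) > 0))
  expect_true(all(pe > 0 & pe < 1 & pt > 0 & pt < 1))
})

test_that("log posterior matches a term-by-term oracle", {
  g <- standard_grid()
  prior <- default_prior(g)
  # empty data: just the prior density
  th <- as.list(prior$mean)
  expect_equal(log_posterior(th, trial_data(k = 4), prior, g),
               sum(dnorm(unlist(th), prior$mean, prior$sd, log = TRUE)))
  # a single patient with both events at fd = 0 under theta = 0 adds
  # log(0.5) twice
  g0 <- dose_grid(c(10, 10 * exp(1)))
  th0 <- list(mu_eff = 0, beta_eff1 = 0, beta_eff2 = 0,
              mu_tox = 0, beta_tox = 0)
  p0 <- prior_spec(rep(0, 5), rep(1, 5))
  base <- log_posterior(th0, trial_data(k = 2), p0, g0)
  one <- trial_data(1L, 1L, 1L, k = 2)
  # all coefficients zero, so both linear predictors vanish at any dose
  lp1 <- log_posterior(th0, one, p0, g0)
  expect_equal(lp1, base + 2 * log(0.5))
  # random datasets against the independent per-patient oracle
  set.seed(21)
  for (i in 1:5) {
    data <- random_trial_data(n = 10)
    theta <- as.list(setNames(rnorm(5), names(prior$mean)))
    expect_equal(log_posterior(theta, data, prior, g),
                 oracle_log_posterior(theta, data, prior, g),
                 tolerance = 1e-10)
  }
})

test_that("log posterior is invariant to patient order", {
  set.seed(31)
  g <- standard_grid()
  prior <- default_prior(g)
  data <- random_trial_data(n = 15)
  theta <- as.list(setNames(rnorm(5), names(prior$mean)))
  perm <- sample(nrow(data))
  shuffled <- trial_data(data$dose_index[perm], data$y_eff[perm],
                         data$y_tox[perm], k = 4)
  expect_equal(log_posterior(theta, data, prior, g),
               log_posterior(theta, shuffled, prior, g))
})

test_that("posterior sampling is seed-reproducible", {
  g <- standard_grid()
  prior <- default_prior(g)
  set.seed(41)
  data <- random_trial_data(n = 9)
  d1 <- sample_posterior(data, prior, g, n_draws = 200, seed = 99,
                         burnin = 100)
  d2 <- sample_posterior(data, prior, g, n_draws = 200, seed = 99,
                         burnin = 100)
  expect_identical(d1$draws, d2$draws)
  d3 <- sample_posterior(data, prior, g, n_draws = 200, seed = 100,
                         burnin = 100)
  expect_false(identical(d1$draws, d3$draws))
})

test_that("with no data the sampler recovers the prior", {
  g <- standard_grid()
  prior <- default_prior(g)
  d <- sample_posterior(trial_data(k = 4), prior, g, n_draws = 8000,
                        seed = 5, burnin = 1000)
  m <- colMeans(d$draws)
  s <- apply(d$draws, 2, sd)
  # autocorrelated chain: allow a generous Monte-Carlo margin
  expect_true(all(abs(m - prior$mean) < 0.12 * prior$sd))
  expect_true(all(abs(s / prior$sd - 1) < 0.12))
  expect_false(d$diagnostics$flagged)
})

test_that("fixed parameters are honoured and draws stay finite", {
  g <- standard_grid()
  prior <- default_prior(g)
  set.seed(51)
  data <- random_trial_data(n = 12)
  d <- sample_posterior(data, prior, g, n_draws = 300, seed = 6,
                        burnin = 200,
                        fixed = c(beta_eff2 = 0, beta_tox = 0.5))
  expect_true(all(d$draws[, "beta_eff2"] == 0))
  expect_true(all(d$draws[, "beta_tox"] == 0.5))
  expect_true(all(is.finite(d$draws)))
})

test_that("posterior expected utility reduces to pointwise utility on a
           degenerate draw set", {
  g <- standard_grid()
  prior <- default_prior(g)
  u <- utility_preset("R2DT1")
  d <- sample_posterior(trial_data(k = 4), prior, g, n_draws = 1,
                        seed = 8, burnin = 10)
  th <- as.list(d$draws[1, ])
  for (j in 1:4) {
    expect_equal(
      posterior_expected_utility(d, g, j, u),
      evaluate_utility(u, prob_efficacy(th, g$centered_log[j]),
                       prob_toxicity(th, g$centered_log[j])))
  }
})

test_that("expected utility under uncertainty is penalised on concave
           gain regions (Jensen)", {
  u <- utility_preset("R2DT1")
  set.seed(61)
  # efficacy probabilities entirely on the concave gain branch
  pe <- runif(500, 0.55, 0.95)
  pt <- rep(0.1, 500)
  expect_lt(mean(evaluate_utility(u, pe, pt)),
            evaluate_utility(u, mean(pe), 0.1))
})

test_that("posterior tail probabilities are exact on constructed draws", {
  g <- standard_grid()
  u <- utility_preset("R2DT1")
  # hand-built draw objects: two-point posteriors
  mk_draws <- function(mat) {
    structure(list(draws = mat,
                   diagnostics = list(flagged = FALSE),
                   provenance = list(n_patients = 0)),
              class = "r2dt_draws")
  }
  # all mass at a very good outcome: never below the contour
  good <- matrix(rep(c(qlogis(0.9), 0, 0, qlogis(0.1), 0), each = 4),
                 nrow = 4,
                 dimnames = list(NULL, c("mu_eff", "beta_eff1", "beta_eff2",
                                         "mu_tox", "beta_tox")))
  tp <- posterior_tail_probs(mk_draws(good), g, u_ref = 0.582,
                             utility = u)
  expect_equal(tp$pr_utility_below, rep(0, 4))
  # all mass at a poor outcome: always below
  bad <- good
  bad[, "mu_eff"] <- qlogis(0.2); bad[, "mu_tox"] <- qlogis(0.6)
  tp <- posterior_tail_probs(mk_draws(bad), g, u_ref = 0.582, utility = u)
  expect_equal(tp$pr_utility_below, rep(1, 4))
  # two-point posterior straddling a threshold
  half <- rbind(good, bad)
  tp <- posterior_tail_probs(mk_draws(half), g, eff_above = 0.5,
                             u_ref = 0.582, utility = u)
  expect_equal(tp$pr_utility_below, rep(0.5, 4))
  expect_equal(tp$pr_eff_above, rep(0.5, 4))
  expect_error(posterior_tail_probs(mk_draws(good), g, eff_above = 1.5),
               "thresholds")
})
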