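# Independent oracles used across tests.  These deliberately re-derive
# quantities from first principles (direct arithmetic, enumeration or
# quadrature) rather than calling the code paths they check.

# Direct transcription of the segmented power utilities with explicit
# endpoint normalisation; scalar only, written without the package's
# transform trick.
oracle_marginal_eff <- function(p, ref, lambda, aG, aL) {
  raw <- function(x) if (x >= ref) (x - ref)^aG else -lambda * (ref - x)^aL
  (raw(p) - raw(0)) / (raw(1) - raw(0))
}
oracle_marginal_tox <- function(p, ref, lambda, aG, aL) {
  raw <- function(x) if (x <= ref) (ref - x)^aG else -lambda * (x - ref)^aL
  (raw(p) - raw(1)) / (raw(0) - raw(1))
}
oracle_joint <- function(kE, kT, uE, uT) {
  kE * uE + kT * uT + (1 - kE - kT) * uE * uT
}

# The reference-dependent stack of the worked examples, evaluated entirely
# through the oracle functions.
oracle_r2dt1 <- function(p_eff, p_tox) {
  uE <- oracle_marginal_eff(p_eff, 0.5, 2, 0.7, 0.7)
  uT <- oracle_marginal_tox(p_tox, 0.35, 2, 0.7, 0.7)
  oracle_joint(0.25, 0.15, uE, uT)
}

# Term-by-term log posterior, one patient at a time (no sufficient
# statistics, no vectorisation).
oracle_log_posterior <- function(theta, data, prior, grid) {
  th <- unlist(theta)
  lp <- 0
  nm <- c("mu_eff", "beta_eff1", "beta_eff2", "mu_tox", "beta_tox")
  for (i in seq_along(nm))
    lp <- lp + dnorm(th[[nm[i]]], prior$mean[[nm[i]]], prior$sd[[nm[i]]],
                     log = TRUE)
  for (i in seq_len(nrow(data))) {
    fd <- grid$centered_log[data$dose_index[i]]
    pe <- 1 / (1 + exp(-(th[["mu_eff"]] + th[["beta_eff1"]] * fd +
                         th[["beta_eff2"]] * fd^2)))
    pt <- 1 / (1 + exp(-(th[["mu_tox"]] + th[["beta_tox"]] * fd)))
    lp <- lp + log(if (data$y_eff[i] == 1) pe else 1 - pe)
    lp <- lp + log(if (data$y_tox[i] == 1) pt else 1 - pt)
  }
  lp
}

# Dense-grid quadrature posterior for the restriction with only mu_eff and
# beta_eff1 free (beta_eff2 and the toxicity parameters fixed).  Returns
# the posterior mean of pi_E at each dose.
oracle_quadrature_pe <- function(data, prior, grid, fixed, half_width = 6,
                                 n_grid = 201) {
  mu <- seq(prior$mean[["mu_eff"]] - half_width * prior$sd[["mu_eff"]],
            prior$mean[["mu_eff"]] + half_width * prior$sd[["mu_eff"]],
            length.out = n_grid)
  b1 <- seq(prior$mean[["beta_eff1"]] - half_width * prior$sd[["beta_eff1"]],
            prior$mean[["beta_eff1"]] + half_width * prior$sd[["beta_eff1"]],
            length.out = n_grid)
  gr <- expand.grid(mu = mu, b1 = b1)
  fd <- grid$centered_log
  # efficacy log likelihood only: the toxicity factor is constant in
  # (mu_eff, beta_eff1) and cancels in the normalisation
  ll <- numeric(nrow(gr))
  for (j in seq_len(grid$k)) {
    nj <- sum(data$dose_index == j)
    if (nj == 0) next
    yj <- sum(data$y_eff[data$dose_index == j])
    eta <- gr$mu + gr$b1 * fd[j] + fixed[["beta_eff2"]] * fd[j]^2
    ll <- ll + yj * eta - nj * log1p(exp(eta))
  }
  lp <- ll + dnorm(gr$mu, prior$mean[["mu_eff"]], prior$sd[["mu_eff"]],
                   log = TRUE) +
    dnorm(gr$b1, prior$mean[["beta_eff1"]], prior$sd[["beta_eff1"]],
          log = TRUE)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  vapply(seq_len(grid$k), function(j) {
    eta <- gr$mu + gr$b1 * fd[j] + fixed[["beta_eff2"]] * fd[j]^2
    sum(w * plogis(eta))
  }, numeric(1))
}

# small random dataset on the standard grid
random_trial_data <- function(n = 12, k = 4) {
  trial_data(sample.int(k, n, replace = TRUE),
             rbinom(n, 1, 0.5), rbinom(n, 1, 0.3), k = k)
}

standard_grid <- function() dose_grid(c(20, 30, 40, 50))
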