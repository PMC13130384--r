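#' Sample the posterior of the dose-response parameters
#'
#' Componentwise adaptive random-walk Metropolis targeting the posterior of
#' the five logistic parameters.  Proposal scales are tuned during burn-in
#' by diminishing batch adaptation towards a 0.44 per-component acceptance
#' rate and then frozen, so the retained draws come from a fixed Markov
#' kernel.  All randomness flows through R's RNG: calling [set.seed()] (or
#' passing `seed`) makes the draws reproducible.
#'
#' @param data A [trial_data()] object (may be empty, in which case the
#'   posterior is the prior).
#' @param prior A [prior_spec()].
#' @param grid A [dose_grid()].
#' @param n_draws Number of retained draws (default 2000).
#' @param seed Optional integer seed set before sampling.
#' @param burnin Burn-in sweeps discarded before retention.
#' @param fixed Optional named numeric vector pinning a subset of
#'   parameters at given values (those components are not sampled); used
#'   for restricted-model validation.
#' @return An object of class `r2dt_draws`: a draws matrix (`n_draws` x 5)
#'   plus provenance (seed, sampler settings, acceptance rates, data size).
#'   Persistently low acceptance is flagged in `diagnostics$flagged`.
#' @export
sample_posterior <- function(data, prior, grid, n_draws = 2000, seed = NULL,
                             burnin = 1000, fixed = NULL) {
  stopifnot(inherits(prior, "r2dt_prior"), inherits(grid, "r2dt_grid"))
  if (n_draws < 1) stop("`n_draws` must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  init <- prior$mean
  free <- rep(TRUE, 5L)
  names(free) <- .param_names
  if (!is.null(fixed)) {
    if (is.null(names(fixed)) || !all(names(fixed) %in% .param_names))
      stop("`fixed` must be named after model parameters", call. = FALSE)
    init[names(fixed)] <- fixed
    free[names(fixed)] <- FALSE
  }
  counts <- .count_data(data, grid$k)
  res <- .rwm_sampler(counts, grid$centered_log, unname(prior$mean),
                      unname(prior$sd), unname(init), unname(free),
                      as.integer(n_draws), as.integer(burnin))
  colnames(res$draws) <- .param_names
  rate <- stats::setNames(res$accept_rate, .param_names)
  structure(list(
    draws = res$draws,
    diagnostics = list(accept_rate = rate,
                       proposal_scale = stats::setNames(res$scale,
                                                        .param_names),
                       flagged = any(rate[free] < 0.05, na.rm = TRUE)),
    provenance = list(seed = seed, n_draws = n_draws, burnin = burnin,
                      n_patients = nrow(data), fixed = fixed)),
    class = "r2dt_draws")
}

#' @export
print.r2dt_draws <- function(x, ...) {
  cat(sprintf("<posterior draws> S = %d (burn-in %d), %d patients\n",
              nrow(x$draws), x$provenance$burnin, x$provenance$n_patients))
  cat("acceptance:",
      paste(sprintf("%s %.2f", names(x$diagnostics$accept_rate),
                    x$diagnostics$accept_rate), collapse = ", "), "\n")
  if (isTRUE(x$diagnostics$flagged))
    cat("warning: low acceptance flagged; inspect mixing\n")
  invisible(x)
}

# S x k matrices of efficacy and toxicity probabilities per draw and dose
.posterior_probs <- function(draws, grid) {
  d <- draws$draws
  fd <- grid$centered_log
  pe <- stats::plogis(d[, "mu_eff"] + outer(d[, "beta_eff1"], fd) +
                      outer(d[, "beta_eff2"], fd^2))
  pt <- stats::plogis(d[, "mu_tox"] + outer(d[, "beta_tox"], fd))
  list(p_eff = pe, p_tox = pt)
}

#' Posterior expected utility of a dose
#'
#' Monte-Carlo average over posterior draws of the joint utility evaluated
#' at the draw's efficacy/toxicity probabilities for the given dose.  The
#' Bayes action treats the next cohort at the dose maximising this
#' quantity.
#'
#' @param draws An [sample_posterior()] result.
#' @param grid A [dose_grid()].
#' @param dose_index Dose index, or `NULL` for all doses.
#' @param utility A [utility_stack()].
#' @return Expected utilities in \[0, 1\] (one per requested dose).
#' @export
posterior_expected_utility <- function(draws, grid, dose_index = NULL,
                                       utility) {
  stopifnot(inherits(draws, "r2dt_draws"), inherits(utility, "r2dt_utility"))
  idx <- if (is.null(dose_index)) seq_len(grid$k) else dose_index
  if (any(idx < 1 | idx > grid$k)) stop("invalid dose index", call. = FALSE)
  pr <- .posterior_probs(draws, grid)
  vapply(idx, function(j)
    mean(evaluate_utility(utility, pr$p_eff[, j], pr$p_tox[, j])),
    numeric(1))
}

#' Posterior tail probabilities used by admissibility and stopping rules
#'
#' For each requested dose, computes Monte-Carlo proportions of draws with
#' (i) efficacy probability above `eff_above`, (ii) toxicity probability
#' below `tox_below`, and (iii) joint utility below the reference utility
#' `u_ref` (a point on the acceptability contour).
#'
#' @inheritParams posterior_expected_utility
#' @param eff_above,tox_below Probability thresholds in (0, 1);
#'   `NA` skips the corresponding column.
#' @param u_ref Reference utility in \[0, 1\] (`NA` skips); requires
#'   `utility`.
#' @param utility A [utility_stack()] (needed when `u_ref` is given).
#' @return A data frame with one row per dose and columns `dose_index`,
#'   `pr_eff_above`, `pr_tox_below`, `pr_utility_below`.
#' @export
posterior_tail_probs <- function(draws, grid, dose_index = NULL,
                                 eff_above = NA, tox_below = NA,
                                 u_ref = NA, utility = NULL) {
  stopifnot(inherits(draws, "r2dt_draws"))
  idx <- if (is.null(dose_index)) seq_len(grid$k) else dose_index
  if (any(idx < 1 | idx > grid$k)) stop("invalid dose index", call. = FALSE)
  for (thr in c(eff_above, tox_below))
    if (!is.na(thr) && (thr <= 0 || thr >= 1))
      stop("probability thresholds must lie in (0, 1)", call. = FALSE)
  if (!is.na(u_ref) && (u_ref < 0 || u_ref > 1))
    stop("`u_ref` must lie in [0, 1]", call. = FALSE)
  pr <- .posterior_probs(draws, grid)
  out <- data.frame(dose_index = idx,
                    pr_eff_above = NA_real_, pr_tox_below = NA_real_,
                    pr_utility_below = NA_real_)
  for (i in seq_along(idx)) {
    j <- idx[i]
    if (!is.na(eff_above))
      out$pr_eff_above[i] <- mean(pr$p_eff[, j] > eff_above)
    if (!is.na(tox_below))
      out$pr_tox_below[i] <- mean(pr$p_tox[, j] < tox_below)
    if (!is.na(u_ref)) {
      if (is.null(utility))
        stop("`utility` is required to evaluate `u_ref` tail", call. = FALSE)
      u <- evaluate_utility(utility, pr$p_eff[, j], pr$p_tox[, j])
      out$pr_utility_below[i] <- mean(u < u_ref)
    }
  }
  out
}

#' Export posterior draws as a data frame
#'
#' @param x An `r2dt_draws` object.
#' @param ... Unused.
#' @return Data frame with a draw index and the five parameter columns.
#' @export
as.data.frame.r2dt_draws <- function(x, ...) {
  data.frame(draw = seq_len(nrow(x$draws)), x$draws)
}
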