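#' Load and validate a trial configuration file
#'
#' Reads a YAML or JSON configuration document (format decided by the file
#' extension; `.json` is parsed as JSON, everything else as YAML) and
#' expands it into validated package objects.  The top level accepts the
#' keys `design`, `doses`, `prior` and `seed`; unknown keys are an error so
#' misspellings cannot pass silently.
#'
#' `design` is either a preset label accepted by [design_preset()] or a
#' mapping with keys `rule_variant`, `cohort_size`, `max_n`,
#' `start_dose_index`, `adm_eff`, `adm_tox`, `contour`, `pu` and a
#' `utility` block (`efficacy`/`toxicity` marginal parameter maps plus a
#' `joint` map with `k_eff`, `k_tox`).  `doses` defaults to the
#' 20/30/40/50 mg/kg grid and `prior` (a map with `mean` and `sd`, five
#' values each) to [default_prior()].
#'
#' @param path Path to the configuration file.
#' @return A list with elements `design` ([design_config()]), `grid`
#'   ([dose_grid()]), `prior` ([prior_spec()]) and `seed` (integer or
#'   `NULL`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping", call. = FALSE)
  known <- c("design", "doses", "prior", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$design)) stop("config needs a `design` entry",
                                call. = FALSE)

  grid <- dose_grid(if (is.null(cfg$doses)) c(20, 30, 40, 50)
                    else as.numeric(cfg$doses))
  prior <- if (is.null(cfg$prior)) default_prior(grid)
           else prior_spec(as.numeric(cfg$prior$mean),
                           as.numeric(cfg$prior$sd))

  design <- if (is.character(cfg$design)) design_preset(cfg$design)
            else .design_from_block(cfg$design)
  list(design = design, grid = grid, prior = prior,
       seed = if (is.null(cfg$seed)) NULL else as.integer(cfg$seed))
}

.design_from_block <- function(blk) {
  known <- c("rule_variant", "cohort_size", "max_n", "start_dose_index",
             "adm_eff", "adm_tox", "contour", "pu", "utility", "label")
  extra <- setdiff(names(blk), known)
  if (length(extra))
    stop("unknown design key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (is.null(blk$utility))
    stop("design block needs a `utility` entry", call. = FALSE)
  u <- blk$utility
  marg <- function(m, orientation) {
    marginal_utility_spec(m$reference, m$loss_aversion, m$exp_gain,
                          m$exp_loss, orientation)
  }
  stack <- utility_stack(marg(u$efficacy, "efficacy"),
                         marg(u$toxicity, "toxicity"),
                         joint_utility_spec(u$joint$k_eff, u$joint$k_tox))
  args <- list(utility = stack)
  if (!is.null(blk$rule_variant)) args$rule_variant <- blk$rule_variant
  for (f in c("cohort_size", "max_n", "start_dose_index", "pu", "label"))
    if (!is.null(blk[[f]])) args[[f]] <- blk[[f]]
  for (f in c("adm_eff", "adm_tox"))
    if (!is.null(blk[[f]])) args[[f]] <- as.numeric(blk[[f]])
  if (!is.null(blk$contour)) {
    args$contour_eff <- blk$contour[[1]]
    args$contour_tox <- blk$contour[[2]]
  }
  do.call(design_config, args)
}

#' Write / read an operating-characteristics table
#'
#' The CSV mirrors the usual reporting layout: one row per dose with the
#' selection percentage and mean number of patients treated, plus an `NDS`
#' row for the percentage of trials that selected no dose.
#'
#' @param oc An `r2dt_oc` object.
#' @param path Output CSV path.
#' @return `write_oc_table()` returns `path` invisibly; `read_oc_table()`
#'   returns the table as a data frame.
#' @export
write_oc_table <- function(oc, path) {
  stopifnot(inherits(oc, "r2dt_oc"))
  k <- length(oc$pct_selection)
  tab <- data.frame(
    dose = c(paste0("dose", seq_len(k)), "NDS"),
    pct_selection = c(oc$pct_selection, oc$pct_nds),
    mean_patients = c(oc$mean_patients, NA_real_))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_oc_table
#' @export
read_oc_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a per-cohort decision trace
#'
#' One row per cohort with the assigned dose, cumulative sample size, the
#' per-dose expected utilities and admissibility flags, and the action
#' taken.
#'
#' @param trial An `r2dt_trial` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_decision_trace <- function(trial, path) {
  stopifnot(inherits(trial, "r2dt_trial"))
  utils::write.csv(trial$trace, path, row.names = FALSE)
  invisible(path)
}

#' Export the joint utility on a probability grid
#'
#' Convenience export for contour plots of the joint utility surface.
#'
#' @param stack A [utility_stack()].
#' @param n Grid resolution per axis.
#' @return A data frame with columns `p_eff`, `p_tox`, `utility`.
#' @export
utility_contour_grid <- function(stack, n = 101) {
  g <- expand.grid(p_eff = seq(0, 1, length.out = n),
                   p_tox = seq(0, 1, length.out = n))
  g$utility <- evaluate_utility(stack, g$p_eff, g$p_tox)
  g
}
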