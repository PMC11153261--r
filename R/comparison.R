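# AIC / relative-likelihood comparison of predictor sets (raw clustering
# indicators vs discrete subgroup membership vs both) across model families.

#' Relative likelihood of models from their AICs
#'
#' `RL_i = exp((min_j AIC_j - AIC_i) / 2)`; the AIC minimiser gets exactly 1
#' and smaller values indicate more information loss relative to the best
#' model.
#'
#' @param aic_values numeric vector of AICs (all finite).
#' @return Relative likelihoods in `(0, 1]`, same order.
#' @export
relative_likelihood <- function(aic_values) {
  if (!length(aic_values) || any(!is.finite(aic_values))) {
    stop("AIC values must be finite and non-empty")
  }
  exp((min(aic_values) - aic_values) / 2)
}

#' Compare predictor sets across all model families
#'
#' Fits every target model three times on identical data with the same
#' estimator -- once with the five baseline clustering indicators as
#' predictors, once with discrete subgroup membership, once with both --
#' and assembles a long grid of AIC, per-row min-max scaled AIC and
#' relative likelihood. Rows are the trajectory parameters (random-intercept
#' models), the outcomes (left-truncated Cox models) and the treatment-step
#' multinomial. A fit difference is flagged significant when the weaker
#' model's RL falls at or below 0.1.
#'
#' @param x a `t2d_cohort`.
#' @param labels named character vector of subgroup labels by id.
#' @param baseline baseline table ([select_baseline()]).
#' @param trajectory_parameters which trajectory parameters to include.
#' @param outcomes which outcomes to include.
#' @param include_treatment include the treatment multinomial row.
#' @param predictor_sets which predictor sets to fit.
#' @return A `comparison_grid` data.frame: `target, family, predictor_set,
#'   AIC, logLik, scaled_AIC, RL, significant`. Failed fits leave `NA`
#'   cells; the row is retained.
#' @export
compare_predictor_sets <- function(x, labels, baseline,
                                   trajectory_parameters =
                                     TRAJECTORY_PARAMETERS,
                                   outcomes = OUTCOMES,
                                   include_treatment = TRUE,
                                   predictor_sets = c("indicators",
                                                      "subgroups", "both")) {
  rows <- list()
  add_row <- function(target, family, set, fitfun) {
    res <- tryCatch(suppressWarnings(fitfun()), error = function(e) NULL)
    rows[[length(rows) + 1L]] <<- data.frame(
      target = target, family = family, predictor_set = set,
      AIC = if (is.null(res)) NA_real_ else res$AIC,
      logLik = if (is.null(res)) NA_real_ else res$logLik)
  }
  for (p in trajectory_parameters) {
    for (set in predictor_sets) {
      add_row(p, "trajectory", set, function() {
        fit_random_intercept(x, p, set, labels, baseline)
      })
    }
  }
  ind_cov <- c("base_age", "base_bmi", "base_hba1c", "base_c_peptide",
               "base_hdl")
  for (oc in outcomes) {
    st <- tryCatch(outcome_table(x, oc, labels, baseline),
                   error = function(e) NULL)
    for (set in predictor_sets) {
      add_row(oc, "cox", set, function() {
        if (is.null(st)) stop("no outcome table")
        cov <- switch(set, indicators = ind_cov, subgroups = "subgroup",
                      both = c("subgroup", ind_cov))
        fit_cox(st, covariates = cov, adjust = "none")
      })
    }
  }
  if (include_treatment) {
    steps <- step_per_interval(x)
    for (set in predictor_sets) {
      add_row("treatment", "multinomial", set, function() {
        fit_multinomial(steps, set, labels, baseline)
      })
    }
  }
  grid <- do.call(rbind, rows)
  grid$scaled_AIC <- NA_real_
  grid$RL <- NA_real_
  for (tg in unique(grid$target)) {
    i <- which(grid$target == tg & is.finite(grid$AIC))
    if (!length(i)) next
    a <- grid$AIC[i]
    rng <- max(a) - min(a)
    grid$scaled_AIC[i] <- if (rng == 0) 0 else (a - min(a)) / rng
    grid$RL[i] <- relative_likelihood(a)
  }
  grid$significant <- !is.na(grid$RL) & grid$RL <= 0.1
  class(grid) <- c("comparison_grid", "data.frame")
  grid
}

#' @export
print.comparison_grid <- function(x, ...) {
  cat("<comparison_grid>", length(unique(x$target)), "targets x",
      length(unique(x$predictor_set)), "predictor sets\n")
  print(as.data.frame(x), digits = 4)
  invisible(x)
}
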