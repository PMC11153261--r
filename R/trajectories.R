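# Subgroup trajectory description (annual mean +/- SD) and random-intercept
# longitudinal models per clinical parameter.

#' Annual per-subgroup summary of a clinical parameter
#'
#' Bins visits by whole years of diabetes duration (`floor(duration)`) and
#' reports, per subgroup and year bin, the number of non-missing values,
#' their mean and their SD. Missing values are omitted. Bins with a single
#' observation report SD 0 with `single_obs = TRUE`.
#'
#' @param x a `t2d_cohort`.
#' @param parameter one of [TRAJECTORY_PARAMETERS].
#' @param labels named character vector of subgroup labels by id.
#' @return data.frame: `subgroup, year, n, mean, sd, single_obs`.
#' @export
annual_summary <- function(x, parameter, labels) {
  validate_cohort(x)
  if (!parameter %in% TRAJECTORY_PARAMETERS) {
    stop("unknown trajectory parameter: ", parameter)
  }
  vis <- x$visits
  v <- vis[[parameter]]
  keep <- !is.na(v) & vis$id %in% names(labels)
  d <- data.frame(subgroup = unname(labels[vis$id[keep]]),
                  year = floor(vis$duration[keep]),
                  value = v[keep])
  if (!nrow(d)) {
    return(data.frame(subgroup = character(0), year = integer(0),
                      n = integer(0), mean = numeric(0), sd = numeric(0),
                      single_obs = logical(0)))
  }
  agg <- aggregate(value ~ subgroup + year, data = d,
                   FUN = function(z) c(n = length(z), mean = mean(z),
                                       sd = if (length(z) > 1) sd(z) else 0))
  out <- data.frame(subgroup = agg$subgroup, year = agg$year,
                    n = as.integer(agg$value[, "n"]),
                    mean = agg$value[, "mean"],
                    sd = agg$value[, "sd"],
                    single_obs = agg$value[, "n"] == 1)
  out <- out[order(out$subgroup, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

traj_model_data <- function(x, parameter, labels, baseline) {
  vis <- x$visits
  v <- vis[[parameter]]
  keep <- !is.na(v) & vis$id %in% names(labels) & vis$id %in% baseline$id
  ind <- x$individuals
  m <- match(vis$id[keep], ind$id)
  bm <- match(vis$id[keep], baseline$id)
  d <- data.frame(id = vis$id[keep],
                  value = v[keep],
                  duration = vis$duration[keep],
                  sex = ind$sex[m],
                  subgroup = unname(labels[vis$id[keep]]),
                  base_age = baseline$age[bm],
                  base_bmi = baseline$bmi[bm],
                  base_hba1c = baseline$hba1c[bm],
                  base_c_peptide = baseline$c_peptide[bm],
                  base_hdl = baseline$hdl[bm])
  d
}

predictor_terms <- function(predictors) {
  ind_terms <- c("base_hba1c", "base_c_peptide", "base_hdl", "base_age",
                 "base_bmi")
  switch(predictors,
         subgroups = "subgroup",
         indicators = ind_terms,
         both = c("subgroup", ind_terms),
         stop("predictors must be one of subgroups/indicators/both"))
}

#' Random-intercept model of a clinical parameter over follow-up
#'
#' Linear mixed model `value ~ fixed effects + (1 | individual)` fitted by
#' maximum likelihood (not REML, so AICs are comparable across fixed-effect
#' structures). The fixed effects are sex, diabetes duration (linear) and
#' the chosen predictor set: discrete subgroup membership (4 contrasts
#' against `reference`), the five baseline clustering indicators, or both.
#'
#' @param x a `t2d_cohort`.
#' @param parameter one of [TRAJECTORY_PARAMETERS].
#' @param predictors `"subgroups"`, `"indicators"` or `"both"`.
#' @param labels named character vector of subgroup labels by id.
#' @param baseline baseline table ([select_baseline()]).
#' @param reference reference subgroup for the contrasts. Default SIDD.
#' @return A `mixed_model_result`: fixed-effect table, variance components,
#'   log-likelihood, AIC, sizes, and the fitted `lmerMod` in `$fit`.
#' @export
fit_random_intercept <- function(x, parameter,
                                 predictors = c("subgroups", "indicators",
                                                "both"),
                                 labels, baseline, reference = "SIDD") {
  predictors <- match.arg(predictors)
  if (!parameter %in% TRAJECTORY_PARAMETERS) {
    stop("unknown trajectory parameter: ", parameter)
  }
  d <- traj_model_data(x, parameter, labels, baseline)
  if (predictors != "indicators") {
    lev <- c(reference, setdiff(SUBGROUPS, reference))
    d$subgroup <- factor(d$subgroup,
                         levels = intersect(lev, unique(d$subgroup)))
  }
  rhs <- c(predictor_terms(predictors), "sex", "duration")
  form <- as.formula(paste("value ~", paste(rhs, collapse = " + "),
                           "+ (1 | id)"))
  fit <- lme4::lmer(form, data = d, REML = FALSE)
  conv <- fit@optinfo$conv$opt
  if (!is.null(conv) && conv != 0) {
    stop("mixed model did not converge (optimizer code ", conv, "): ",
         paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "))
  }
  if (lme4::isSingular(fit)) {
    warning("singular fit: random-intercept variance estimated at boundary")
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri_var <- vc$vcov[vc$grp == "id"]
  resid_var <- vc$vcov[vc$grp == "Residual"]
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  ll <- logLik(fit)
  structure(list(
    parameter = parameter,
    predictors = predictors,
    fixed = data.frame(term = names(fe), estimate = unname(fe),
                       se = unname(se)),
    ri_var = ri_var,
    resid_var = resid_var,
    logLik = as.numeric(ll),
    df = attr(ll, "df"),
    AIC = AIC(fit),
    n_obs = nrow(d),
    n_individuals = length(unique(d$id)),
    fit = fit), class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat("<mixed_model_result>", x$parameter, "~", x$predictors,
      sprintf(" (n_obs %d, n_ind %d)\n", x$n_obs, x$n_individuals))
  print(x$fixed, digits = 4)
  cat(sprintf("random-intercept var %.4g, residual var %.4g\n",
              x$ri_var, x$resid_var))
  cat(sprintf("logLik %.2f  AIC %.2f\n", x$logLik, x$AIC))
  invisible(x)
}
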