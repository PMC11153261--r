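# Time-to-first-event analysis by subgroup: Kaplan-Meier cumulative
# incidence with delayed entry, pairwise logrank with Benjamini-Hochberg
# correction, left-truncated Cox models with Efron ties and Schoenfeld
# proportional-hazards checks.

#' Build a per-individual survival table for one outcome
#'
#' Joins the cohort's first-event records for `outcome` with subgroup
#' labels, baseline age/sex and the study entry time (the baseline
#' observation duration: on a diabetes-duration timescale individuals enter
#' the risk set only from their baseline observation onward).
#'
#' @param x a `t2d_cohort`.
#' @param outcome one of [OUTCOMES].
#' @param labels named character vector of subgroup labels by id.
#' @param baseline baseline table ([select_baseline()]); source of `entry`
#'   (= `baseline_duration`), baseline `age` and indicator values.
#' @return data.frame `id, time, observed, entry, subgroup, age, sex` plus
#'   the baseline indicators as `base_*` columns. Rows with `entry >= time`
#'   are dropped with a warning.
#' @export
outcome_table <- function(x, outcome, labels, baseline) {
  validate_cohort(x)
  if (!outcome %in% OUTCOMES) stop("unknown outcome: ", outcome)
  ev <- x$events[x$events$outcome == outcome, , drop = FALSE]
  ev <- ev[ev$id %in% names(labels) & ev$id %in% baseline$id, , drop = FALSE]
  bm <- match(ev$id, baseline$id)
  im <- match(ev$id, x$individuals$id)
  d <- data.frame(id = ev$id, time = ev$time, observed = ev$observed,
                  entry = baseline$baseline_duration[bm],
                  subgroup = unname(labels[ev$id]),
                  age = baseline$age[bm],
                  sex = x$individuals$sex[im],
                  base_age = baseline$age[bm],
                  base_bmi = baseline$bmi[bm],
                  base_hba1c = baseline$hba1c[bm],
                  base_c_peptide = baseline$c_peptide[bm],
                  base_hdl = baseline$hdl[bm])
  bad <- d$entry >= d$time
  if (any(bad)) {
    warning(sum(bad), " record(s) with entry >= event/censor time dropped")
    d <- d[!bad, , drop = FALSE]
  }
  rownames(d) <- NULL
  d
}

surv_object <- function(surv) {
  if (!is.null(surv$entry) && any(surv$entry > 0)) {
    survival::Surv(surv$entry, surv$time, surv$observed)
  } else {
    survival::Surv(surv$time, surv$observed)
  }
}

#' Kaplan-Meier cumulative incidence by group
#'
#' One minus the Kaplan-Meier survival estimate per group, with delayed
#' entry respected in the risk sets when an `entry` column is present, and
#' the value extracted at `eval_time`.
#'
#' @param surv data.frame with `time`, `observed` and optionally `entry`.
#' @param groups group label per row.
#' @param eval_time time (years since diagnosis) at which to read off the
#'   cumulative incidence. Default 10.
#' @return list with `curves` (long data.frame `group, time, cuminc,
#'   n_risk`) and `at_eval` (named vector of cumulative incidences at
#'   `eval_time`). Groups with zero members are omitted with a warning.
#' @export
km_cumulative_incidence <- function(surv, groups, eval_time = 10) {
  groups <- as.character(groups)
  empty <- setdiff(unique(groups), groups[!is.na(surv$time)])
  if (length(empty)) warning("group(s) with zero members omitted: ",
                             paste(empty, collapse = ", "))
  d <- data.frame(surv, group = groups)
  fit <- survival::survfit(surv_object(d) ~ group, data = d)
  strata_names <- if (is.null(fit$strata)) {
    unique(groups)
  } else {
    sub("^group=", "", names(fit$strata))
  }
  grp <- if (is.null(fit$strata)) {
    rep(strata_names[1], length(fit$time))
  } else {
    rep(strata_names, fit$strata)
  }
  curves <- data.frame(group = grp, time = fit$time,
                       cuminc = 1 - fit$surv, n_risk = fit$n.risk)
  sm <- summary(fit, times = eval_time, extend = TRUE)
  at_grp <- if (is.null(sm$strata)) strata_names[1] else
    sub("^group=", "", as.character(sm$strata))
  at_eval <- setNames(1 - sm$surv, at_grp)
  list(curves = curves, at_eval = at_eval, eval_time = eval_time)
}

logrank_test <- function(surv, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  d <- data.frame(surv, g = g)
  if (!is.null(d$entry) && any(d$entry > 0)) {
    # survdiff has no delayed-entry support; the Cox partial-likelihood
    # score test with a group factor is the logrank statistic
    fit <- survival::coxph(surv_object(d) ~ g, data = d)
    stat <- fit$score
    df <- nlevels(g) - 1
  } else {
    sd <- survival::survdiff(surv_object(d) ~ g, data = d)
    stat <- sd$chisq
    df <- length(sd$n) - 1
  }
  list(statistic = unname(stat), df = df,
       p = pchisq(stat, df, lower.tail = FALSE))
}

#' Global and pairwise logrank tests with BH correction
#'
#' A global logrank test across all groups plus every pairwise test, with
#' Benjamini-Hochberg adjustment applied across the pairwise p-values of
#' this outcome (the within-outcome family of 10 comparisons for five
#' groups).
#'
#' @param surv data.frame with `time`, `observed` and optionally `entry`.
#' @param groups group label per row.
#' @return list with `global` (statistic/df/p), `raw` and `adjusted`
#'   symmetric p-value matrices, and `no_event_groups` (flagged groups that
#'   participate without any observed event).
#' @export
logrank_pairwise <- function(surv, groups) {
  groups <- as.character(groups)
  lev <- unique(groups)
  lev <- c(intersect(SUBGROUPS, lev), sort(setdiff(lev, SUBGROUPS)))
  if (length(lev) < 2) stop("need >= 2 groups with events")
  no_events <- lev[vapply(lev, function(l) {
    !any(surv$observed[groups == l])
  }, logical(1))]
  if (length(no_events)) {
    warning("group(s) without events: ", paste(no_events, collapse = ", "))
  }
  global <- logrank_test(surv, groups)
  np <- length(lev)
  raw <- matrix(NA_real_, np, np, dimnames = list(lev, lev))
  for (a in seq_len(np - 1)) {
    for (b in seq((a + 1), np)) {
      i <- groups %in% c(lev[a], lev[b])
      raw[a, b] <- raw[b, a] <- logrank_test(surv[i, , drop = FALSE],
                                             groups[i])$p
    }
  }
  pv <- raw[upper.tri(raw)]
  adj <- raw
  adj[upper.tri(adj)] <- bh_adjust(pv)
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  list(global = global, raw = raw, adjusted = adj,
       no_event_groups = no_events,
       adjustment = "Benjamini-Hochberg within outcome")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1, order-preserving
#' with the input indices.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Left-truncated Cox model for one outcome
#'
#' Cox regression on the diabetes-duration timescale with delayed entry at
#' each individual's baseline observation, Efron tie handling, Wald 95\%
#' CIs, and a Schoenfeld residual test per model term (violation of
#' proportional hazards flagged at p < 0.05).
#'
#' @param surv data.frame with `time`, `observed`, optionally `entry`, and
#'   the covariate columns named in `covariates`.
#' @param covariates character vector of covariate column names; a
#'   `subgroup` covariate is encoded as contrasts against `reference`.
#' @param adjust `"none"` or `"age_sex"` (adds baseline age and sex).
#' @param reference reference subgroup. Default MDH.
#' @return A `cox_result`: coefficient table with HRs, 95\% CIs and
#'   per-term Schoenfeld p-values, event count, and the `coxph` fit.
#' @export
fit_cox <- function(surv, covariates = "subgroup",
                    adjust = c("none", "age_sex"), reference = "MDH") {
  adjust <- match.arg(adjust)
  if (!any(surv$observed)) stop("no events observed; cannot fit Cox model")
  d <- surv
  if ("subgroup" %in% covariates) {
    d$subgroup <- factor(d$subgroup,
                         levels = c(reference,
                                    setdiff(unique(d$subgroup), reference)))
  }
  if (adjust == "age_sex") covariates <- union(covariates, c("age", "sex"))
  keep <- character(0)
  for (cv in covariates) {
    if (length(unique(d[[cv]])) < 2) {
      warning("covariate '", cv, "' is constant; dropped")
    } else {
      keep <- c(keep, cv)
    }
  }
  if (!length(keep)) stop("no non-constant covariates left")
  form <- as.formula(paste("surv_object(d) ~", paste(keep, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(form, data = d, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w))) {
        stop("monotone likelihood / separation in Cox fit: ",
             conditionMessage(w))
      }
      invokeRestart("muffleWarning")
    })
  co <- coef(fit)
  se <- sqrt(diag(fit$var))
  zph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
  sch <- rep(NA_real_, length(co))
  if (!is.null(zph)) {
    zt <- zph$table
    terms_here <- rownames(zt)
    for (i in seq_along(co)) {
      hit <- which(vapply(terms_here,
                          function(tt) startsWith(names(co)[i], tt),
                          logical(1)))
      if (length(hit)) sch[i] <- zt[hit[1], "p"]
    }
  }
  tab <- data.frame(term = names(co),
                    loghr = unname(co),
                    se = unname(se),
                    hr = exp(unname(co)),
                    lower = exp(unname(co) - qnorm(0.975) * se),
                    upper = exp(unname(co) + qnorm(0.975) * se),
                    schoenfeld_p = sch,
                    ph_violation = !is.na(sch) & sch < 0.05)
  structure(list(table = tab,
                 n = fit$n,
                 n_events = fit$nevent,
                 reference = reference,
                 adjust = adjust,
                 schoenfeld = if (is.null(zph)) NULL else zph$table,
                 logLik = as.numeric(fit$loglik[2]),
                 AIC = AIC(fit),
                 fit = fit), class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat("<cox_result> events:", x$n_events, "/", x$n,
      " reference:", x$reference, " adjust:", x$adjust, "\n")
  print(x$table, digits = 3)
  invisible(x)
}
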