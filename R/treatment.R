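# ATC-code -> treatment-step classification, per-year step assignment,
# subgroup pattern summaries and multinomial logistic treatment models.
#
# The six mutually exclusive steps follow the primary-care escalation
# ladder: no treatment (diet and exercise), CVD-prevention treatment only
# (ATC C01-C10), step 1 (metformin A10BA02 or the glinides under A10BX),
# step 2 (adding a sulfonylurea, A10BB), step 3 (adding insulin, A10A), and
# "other OAD" (DPP-4 inhibitors A10BH, GLP-1 analogues A10BJ,
# alpha-glucosidase inhibitors A10BF, SGLT2 inhibitors A10BK,
# thiazolidinediones A10BG, liraglutide A10BX07, dapagliflozin A10BX09).

.OTHER_OAD_PREFIX <- c("A10BH", "A10BJ", "A10BF", "A10BK", "A10BG")
.OTHER_OAD_EXACT <- c("A10BX07", "A10BX09")

split_atc <- function(s) {
  if (length(s) == 1 && grepl(";", s)) s <- strsplit(s, ";", fixed = TRUE)[[1]]
  s <- toupper(trimws(s))
  s[nzchar(s)]
}

has_prefix <- function(codes, prefix) any(startsWith(codes, prefix))

#' Classify a set of ATC codes into a treatment step
#'
#' Deterministic, order-independent mapping of the active ATC codes at an
#' observation to exactly one step. The default precedence Step3 > Step2 >
#' Step1 > OtherOAD > OnlyCVD > NoTreatment treats the observed step as the
#' highest rung of the cumulative escalation ladder ("adding" drugs), with
#' OtherOAD assigned only when no ladder drug is present;
#' `other_oad_rule = "other_oad_first"` instead ranks OtherOAD above steps 1
#' and 2. A10BX07 (liraglutide) and A10BX09 (dapagliflozin) classify as
#' OtherOAD and are excluded from the generic A10BX glinide rule. Matching
#' is case-insensitive string-prefix on canonical codes; malformed codes are
#' ignored with a warning.
#'
#' @param atc_codes character vector of ATC codes, or a single
#'   semicolon-joined string.
#' @param other_oad_rule `"ladder_first"` (default) or `"other_oad_first"`.
#' @return One of [TREATMENT_STEPS].
#' @export
classify_treatment_step <- function(atc_codes,
                                    other_oad_rule = c("ladder_first",
                                                       "other_oad_first")) {
  other_oad_rule <- match.arg(other_oad_rule)
  codes <- split_atc(atc_codes)
  ok <- grepl("^[A-Z]\\d{2}([A-Z]{1,2}(\\d{2})?)?$", codes)
  if (any(!ok)) {
    warning("malformed ATC code(s) ignored: ",
            paste(codes[!ok], collapse = ", "))
    codes <- codes[ok]
  }
  is_other <- any(codes %in% .OTHER_OAD_EXACT) ||
    any(vapply(.OTHER_OAD_PREFIX, function(p) has_prefix(codes, p),
               logical(1)))
  glinide <- setdiff(codes[startsWith(codes, "A10BX")], .OTHER_OAD_EXACT)
  is_step1 <- has_prefix(codes, "A10BA02") || length(glinide) > 0
  is_step2 <- has_prefix(codes, "A10BB")
  is_step3 <- has_prefix(codes, "A10A")
  is_cvd <- any(grepl("^C(0[1-9]|10)", codes))
  if (other_oad_rule == "ladder_first") {
    if (is_step3) return("Step3")
    if (is_step2) return("Step2")
    if (is_step1) return("Step1")
    if (is_other) return("OtherOAD")
  } else {
    if (is_step3) return("Step3")
    if (is_other) return("OtherOAD")
    if (is_step2) return("Step2")
    if (is_step1) return("Step1")
  }
  if (is_cvd) return("OnlyCVD")
  "NoTreatment"
}

#' Treatment step per individual and duration year
#'
#' For each year bin `[y, y+1)` with at least one visit, the step is
#' classified from the codes of the earliest visit in the bin (first
#' available observation). Bins without visits are absent: no carry-forward,
#' and censoring is ignored, accepting that the most intensive steps are
#' underestimated late in follow-up.
#'
#' @param x a `t2d_cohort`.
#' @param other_oad_rule passed to [classify_treatment_step()].
#' @return data.frame `id, year, step`.
#' @export
step_per_interval <- function(x, other_oad_rule = "ladder_first") {
  validate_cohort(x)
  vis <- x$visits
  if (!nrow(vis)) return(data.frame(id = character(0), year = integer(0),
                                    step = character(0)))
  yr <- floor(vis$duration)
  key <- paste(vis$id, yr)
  ord <- order(vis$id, yr, vis$duration)
  first <- ord[!duplicated(key[ord])]
  out <- data.frame(id = vis$id[first], year = as.integer(yr[first]),
                    step = vapply(vis$atc_codes[first], function(s) {
                      classify_treatment_step(s, other_oad_rule)
                    }, character(1), USE.NAMES = FALSE))
  out <- out[order(out$id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Treatment-step proportions per subgroup and year
#'
#' Exact rational proportions of individuals in each step within every
#' (subgroup, year) cell with at least one individual; cells sum to 1.
#' These are the numbers behind per-subgroup area graphs of medication
#' patterns.
#'
#' @param step_table output of [step_per_interval()].
#' @param labels named character vector of subgroup labels by id.
#' @return data.frame `subgroup, year, step, n, proportion`.
#' @export
step_area_summary <- function(step_table, labels) {
  d <- step_table[step_table$id %in% names(labels), , drop = FALSE]
  d$subgroup <- unname(labels[d$id])
  tab <- aggregate(list(n = rep(1L, nrow(d))),
                   by = list(subgroup = d$subgroup, year = d$year,
                             step = d$step),
                   FUN = sum)
  tot <- aggregate(list(total = tab$n),
                   by = list(subgroup = tab$subgroup, year = tab$year),
                   FUN = sum)
  m <- match(paste(tab$subgroup, tab$year),
             paste(tot$subgroup, tot$year))
  tab$proportion <- tab$n / tot$total[m]
  tab <- tab[order(tab$subgroup, tab$year,
                   match(tab$step, TREATMENT_STEPS)), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Multinomial logistic model of treatment steps
#'
#' Multinomial logit with the treatment step as outcome, NoTreatment as the
#' reference category, and the chosen predictor set (discrete subgroups
#' against the `reference_subgroup`, the baseline clustering indicators, or
#' both) plus diabetes duration and sex as covariates. Fitted by maximum
#' likelihood; relative-risk ratios are the exponentiated coefficients.
#'
#' @param step_table output of [step_per_interval()].
#' @param predictors `"subgroups"`, `"indicators"` or `"both"`.
#' @param labels named character vector of subgroup labels by id.
#' @param baseline baseline table ([select_baseline()]); provides sex and
#'   the baseline indicators.
#' @param reference_subgroup reference subgroup for the contrasts (default
#'   MD, so the Step3-vs-NoTreatment SIDD coefficient is the
#'   insulin-escalation contrast of interest).
#' @return A `multinomial_result`: long coefficient table with RRRs and
#'   95\% CIs, log-likelihood, AIC and the `multinom` fit.
#' @export
fit_multinomial <- function(step_table,
                            predictors = c("subgroups", "indicators",
                                           "both"),
                            labels, baseline, reference_subgroup = "MD") {
  predictors <- match.arg(predictors)
  d <- step_table[step_table$id %in% names(labels) &
                    step_table$id %in% baseline$id, , drop = FALSE]
  bm <- match(d$id, baseline$id)
  lev <- c(reference_subgroup, setdiff(SUBGROUPS, reference_subgroup))
  d$subgroup <- factor(unname(labels[d$id]),
                       levels = intersect(lev, unique(unname(labels[d$id]))))
  d$sex <- baseline$sex[bm]
  d$duration <- d$year
  d$base_age <- baseline$age[bm]
  d$base_bmi <- baseline$bmi[bm]
  d$base_hba1c <- baseline$hba1c[bm]
  d$base_c_peptide <- baseline$c_peptide[bm]
  d$base_hdl <- baseline$hdl[bm]
  present <- intersect(TREATMENT_STEPS, unique(d$step))
  dropped <- setdiff(TREATMENT_STEPS, present)
  if (length(dropped)) {
    warning("empty step category(ies) dropped: ",
            paste(dropped, collapse = ", "))
  }
  if (length(present) < 2) stop("need >= 2 observed step categories")
  d$step <- factor(d$step, levels = present)
  rhs <- c(predictor_terms(predictors), "duration", "sex")
  form <- as.formula(paste("step ~", paste(rhs, collapse = " + ")))
  fit <- nnet::multinom(form, data = d, Hess = TRUE, trace = FALSE,
                        maxit = 2000, reltol = 1e-15)
  cf <- coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, 1, dimnames = list(levels(d$step)[2],
                                                            names(cf)))
  se_all <- sqrt(diag(vcov(fit)))
  long <- do.call(rbind, lapply(rownames(cf), function(cat) {
    terms <- colnames(cf)
    est <- cf[cat, ]
    keys <- paste(cat, terms, sep = ":")
    # with only two categories vcov names carry no category prefix
    if (!all(keys %in% names(se_all))) keys <- terms
    se <- se_all[keys]
    data.frame(category = cat, term = terms, estimate = unname(est),
               se = unname(se),
               rrr = exp(unname(est)),
               lower = exp(unname(est) - qnorm(0.975) * se),
               upper = exp(unname(est) + qnorm(0.975) * se))
  }))
  rownames(long) <- NULL
  ll <- logLik(fit)
  structure(list(coefficients = long,
                 reference_category = levels(d$step)[1],
                 reference_subgroup = reference_subgroup,
                 predictors = predictors,
                 logLik = as.numeric(ll),
                 df = attr(ll, "df"),
                 AIC = AIC(fit),
                 n = nrow(d),
                 fit = fit), class = "multinomial_result")
}

#' @export
print.multinomial_result <- function(x, ...) {
  cat("<multinomial_result> steps vs", x$reference_category,
      " predictors:", x$predictors, " n:", x$n, "\n")
  print(x$coefficients, digits = 3)
  cat(sprintf("logLik %.2f  AIC %.2f\n", x$logLik, x$AIC))
  invisible(x)
}
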