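test_that("ATC sets classify to the documented treatment steps", {
  expect_identical(classify_treatment_step(character(0)), "NoTreatment")
  expect_identical(classify_treatment_step("C07AB02"), "OnlyCVD")
  expect_identical(classify_treatment_step("C10AA01"), "OnlyCVD")
  expect_identical(classify_treatment_step("A10BA02"), "Step1")
  expect_identical(classify_treatment_step("A10BX02"), "Step1")  # glinide
  expect_identical(classify_treatment_step(c("A10BA02", "A10BB01")), "Step2")
  expect_identical(classify_treatment_step(c("A10BA02", "A10BB01",
                                             "A10AB01")), "Step3")
  expect_identical(classify_treatment_step("A10AE04"), "Step3")  # insulin
  # the named exceptions leave the generic glinide rule
  expect_identical(classify_treatment_step("A10BX07"), "OtherOAD")
  expect_identical(classify_treatment_step("A10BX09"), "OtherOAD")
  for (code in c("A10BH01", "A10BJ02", "A10BF01", "A10BK01", "A10BG03")) {
    expect_identical(classify_treatment_step(code), "OtherOAD")
  }
  # ladder precedence: OtherOAD only without ladder drugs
  expect_identical(classify_treatment_step(c("A10BH01", "A10BA02")), "Step1")
  expect_identical(
    classify_treatment_step(c("A10BH01", "A10BA02"),
                            other_oad_rule = "other_oad_first"), "OtherOAD")
  # CVD drugs never outrank glucose treatment
  expect_identical(classify_treatment_step(c("C09AA05", "A10BB01")), "Step2")
  # semicolon-joined input and case-insensitivity
  expect_identical(classify_treatment_step("a10ba02;a10bb01"), "Step2")
  expect_warning(out <- classify_treatment_step(c("???", "A10BA02")),
                 "malformed")
  expect_identical(out, "Step1")
})

test_that("classification is permutation-invariant and monotone in additions", {
  pool <- c("A10BA02", "A10BB01", "A10AB01", "A10BH01", "A10BX09",
            "C07AB02", "C10AA01")
  rank_of <- function(step) {
    match(step, c("NoTreatment", "OnlyCVD", "OtherOAD",
                  "Step1", "Step2", "Step3"))
  }
  set.seed(13)
  for (r in 1:50) {
    s <- sample(pool, sample(0:4, 1))
    expect_identical(classify_treatment_step(s),
                     classify_treatment_step(rev(s)))
    extra <- sample(setdiff(pool, s), 1)
    expect_gte(rank_of(classify_treatment_step(c(s, extra))),
               rank_of(classify_treatment_step(s)))
  }
})

test_that("yearly steps come from the first observation in each year bin", {
  ind <- data.frame(id = "a", sex = "M", age_at_diagnosis = 50,
                    gad_positive = FALSE)
  vis <- data.frame(id = "a", duration = c(1.1, 1.8, 3.0),
                    bmi = 30, hba1c = 50, hdl = 1.1, c_peptide = 1,
                    sbp = 140, dbp = 80, creatinine = 80, triglycerides = 2,
                    total_chol = 5, ldl = 3,
                    atc_codes = c("A10BA02", "A10AB01;A10BA02", ""))
  st <- step_per_interval(cohort(ind, vis))
  expect_equal(st$step[st$year == 1], "Step1")  # first visit, not the later
  expect_equal(st$step[st$year == 3], "NoTreatment")
  expect_false(2 %in% st$year)  # no visit, no record, no carry-forward
  expect_false(4 %in% st$year)

  sim <- simulate_cohort(default_params("DCS", n_individuals = 80, seed = 3))
  st2 <- step_per_interval(sim$cohort)
  vis2 <- sim$cohort$visits
  expect_equal(nrow(st2),
               nrow(unique(data.frame(vis2$id, floor(vis2$duration)))))
})

test_that("area summaries are exact proportions summing to one", {
  steps <- data.frame(id = c("a", "b", "c"), year = 1,
                      step = c("Step1", "Step1", "Step3"))
  labels <- c(a = "MD", b = "MD", c = "MD")
  area <- step_area_summary(steps, labels)
  expect_equal(area$proportion[area$step == "Step1"], 2 / 3)
  expect_equal(area$proportion[area$step == "Step3"], 1 / 3)

  sim <- simulate_cohort(default_params("DCS", n_individuals = 150, seed = 9))
  st <- step_per_interval(sim$cohort)
  area2 <- step_area_summary(st, sim$true_labels)
  totals <- tapply(area2$proportion, paste(area2$subgroup, area2$year), sum)
  expect_equal(as.numeric(totals), rep(1, length(totals)))
})

test_that("multinomial fits recover known coefficients", {
  set.seed(31)
  n_ind <- 900
  ids <- sprintf("p%04d", seq_len(n_ind))
  sub <- sample(c("MD", "SIDD"), n_ind, replace = TRUE)
  sex <- sample(c("M", "F"), n_ind, replace = TRUE)
  rows <- list()
  truth <- list(Step1 = c(int = 0.5, sidd = 1.0, dur = 0.10, sexM = 0.3),
                Step3 = c(int = -1.5, sidd = 2.0, dur = 0.20, sexM = 0.1))
  for (i in seq_len(n_ind)) {
    for (y in 0:5) {
      eta1 <- truth$Step1[["int"]] + truth$Step1[["sidd"]] * (sub[i] == "SIDD") +
        truth$Step1[["dur"]] * y + truth$Step1[["sexM"]] * (sex[i] == "M")
      eta3 <- truth$Step3[["int"]] + truth$Step3[["sidd"]] * (sub[i] == "SIDD") +
        truth$Step3[["dur"]] * y + truth$Step3[["sexM"]] * (sex[i] == "M")
      pr <- c(1, exp(eta1), exp(eta3))
      pr <- pr / sum(pr)
      rows[[length(rows) + 1]] <- data.frame(
        id = ids[i], year = y,
        step = sample(c("NoTreatment", "Step1", "Step3"), 1, prob = pr))
    }
  }
  steps <- do.call(rbind, rows)
  baseline <- data.frame(id = ids, sex = sex, age = 55, bmi = 30,
                         hba1c = 55, c_peptide = 1.2, hdl = 1.2,
                         baseline_duration = 0.2)
  fit <- suppressWarnings(
    fit_multinomial(steps, "subgroups", setNames(sub, ids), baseline))
  cf <- fit$coefficients
  pick <- function(cat, term) cf[cf$category == cat & cf$term == term, ]
  for (cat in c("Step1", "Step3")) {
    tr <- truth[[cat]]
    expect_lt(abs(pick(cat, "subgroupSIDD")$estimate - tr[["sidd"]]),
              3 * pick(cat, "subgroupSIDD")$se)
    expect_lt(abs(pick(cat, "duration")$estimate - tr[["dur"]]),
              3 * pick(cat, "duration")$se)
    expect_lt(abs(pick(cat, "sexM")$estimate - tr[["sexM"]]),
              3 * pick(cat, "sexM")$se)
  }
  expect_equal(pick("Step3", "subgroupSIDD")$rrr,
               exp(pick("Step3", "subgroupSIDD")$estimate))
})

test_that("two-category multinomial reduces to binary logistic regression", {
  set.seed(41)
  n <- 800
  ids <- sprintf("q%04d", seq_len(n))
  sub <- sample(c("MD", "SIRD"), n, replace = TRUE)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  year <- sample(0:8, n, replace = TRUE)
  eta <- -0.5 + 0.8 * (sub == "SIRD") + 0.1 * year + 0.2 * (sex == "M")
  y <- rbinom(n, 1, plogis(eta))
  steps <- data.frame(id = ids, year = year,
                      step = ifelse(y == 1, "Step3", "NoTreatment"))
  baseline <- data.frame(id = ids, sex = sex, age = 55, bmi = 30,
                         hba1c = 55, c_peptide = 1.2, hdl = 1.2,
                         baseline_duration = 0.2)
  fit <- suppressWarnings(
    fit_multinomial(steps, "subgroups", setNames(sub, ids), baseline))
  glm_fit <- glm(y ~ I(sub == "SIRD") + year + sex2,
                 data = data.frame(y = y, sub = sub, year = year,
                                   sex2 = sex),
                 family = binomial())
  got <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(got[c("(Intercept)", "subgroupSIRD", "duration",
                            "sexM")]),
               unname(coef(glm_fit)), tolerance = 1e-6)
})
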