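# Shared fixtures and independent oracles for the test suite. The oracles
# are deliberately naive (direct summation, recursion, enumeration) and do
# not share code paths with the package implementations they check.

# tiny hand-built cohort: 3 individuals, assorted visits and events
toy_cohort <- function() {
  individuals <- data.frame(
    id = c("a", "b", "c"),
    sex = c("M", "F", "M"),
    age_at_diagnosis = c(50, 62, 41),
    gad_positive = c(FALSE, FALSE, FALSE))
  visits <- data.frame(
    id = c("a", "a", "a", "b", "c"),
    duration = c(0.3, 1.5, 0.9, 0.1, 2.5),
    bmi = c(28, 29, 28.5, 31, 27),
    hba1c = c(55, 60, 58, 48, 70),
    hdl = c(1.2, 1.1, 1.15, 1.4, 0.9),
    c_peptide = c(0.9, 1.0, 0.95, 1.3, 0.7),
    sbp = c(140, 138, 139, 150, 128),
    dbp = c(85, 84, 83, 90, 78),
    creatinine = c(80, 82, 81, 75, 90),
    triglycerides = c(2.0, 2.1, 2.0, 1.5, 2.4),
    total_chol = c(5.1, 5.0, 5.0, 4.8, 5.5),
    ldl = c(3.1, 3.0, 3.0, 2.9, 3.4),
    atc_codes = c("A10BA02", "A10BA02;A10BB01", "", "C07AB02", ""))
  events <- data.frame(
    id = c("a", "b"),
    outcome = c("AMI", "AMI"),
    time = c(5.2, 8.1),
    observed = c(TRUE, FALSE))
  cohort(individuals, visits, events, name = "toy")
}

# well-separated mixture: published DCS means with SDs shrunk 5-fold
sep_params <- function(n = 2000, seed = 1L) {
  scale_profile_sds(default_params("DCS", n_individuals = n, seed = seed),
                    0.2)
}

# baseline table reshaped as a single follow-up window, values unchanged
baseline_as_window <- function(baseline, label = "[0,2)") {
  data.frame(id = baseline$id, sex = baseline$sex, window = label,
             age = baseline$age, bmi = baseline$bmi,
             hba1c = baseline$hba1c, c_peptide = baseline$c_peptide,
             hdl = baseline$hdl)
}

# direct-summation agreement oracle over two label vectors
oracle_agreement <- function(ref, cand, levels) {
  n <- length(ref)
  k <- length(levels)
  conf <- matrix(0, k, k, dimnames = list(levels, levels))
  for (i in seq_len(n)) conf[ref[i], cand[i]] <- conf[ref[i], cand[i]] + 1
  acc <- sum(diag(conf)) / n
  pe <- 0
  for (c1 in seq_len(k)) pe <- pe + sum(conf[c1, ]) * sum(conf[, c1]) / n^2
  kap <- (acc - pe) / (1 - pe)
  sens <- spec <- sa <- numeric(k)
  for (c1 in seq_len(k)) {
    rowc <- sum(conf[c1, ])
    colc <- sum(conf[, c1])
    sens[c1] <- if (rowc > 0) conf[c1, c1] / rowc else NA_real_
    spec[c1] <- (n - rowc - colc + conf[c1, c1]) / (n - rowc)
    sa[c1] <- if (rowc + colc > 0) 2 * conf[c1, c1] / (rowc + colc) else
      NA_real_
  }
  list(confusion = conf, accuracy = acc, kappa = kap, sensitivity = sens,
       specificity = spec, specific_agreement = sa)
}

# brute-force Benjamini-Hochberg: min over the tail of m * p_(k) / k
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    tail_vals <- vapply(i:m, function(k) m * sorted[k] / k, numeric(1))
    adj[i] <- min(1, min(tail_vals))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# recursive DFS over assignments: independent of the permutation-list
# enumeration used by the implementation
oracle_assignment_cost <- function(cost) {
  n <- nrow(cost)
  best <- Inf
  recurse <- function(row, used, acc) {
    if (row > n) {
      if (acc < best) best <<- acc
      return(invisible())
    }
    for (col in seq_len(n)) {
      if (!used[col] && acc + cost[row, col] < best) {
        used[col] <- TRUE
        recurse(row + 1, used, acc + cost[row, col])
        used[col] <- FALSE
      }
    }
  }
  recurse(1, logical(n), 0)
  best
}

# builds a minimal cohort carrying one longitudinal parameter generated
# from a known random-intercept model, plus the matching label/baseline
# tables needed by the fitting interface
sim_lmm_cohort <- function(n_ind = 150, n_vis = 6, offsets, sigma_b = 3,
                           sigma_e = 2, slope = 0.5, sex_eff = 2,
                           intercept = 80, seed = 1) {
  set.seed(seed)
  ids <- sprintf("p%04d", seq_len(n_ind))
  subgroups <- sample(names(offsets), n_ind, replace = TRUE)
  sex <- sample(c("M", "F"), n_ind, replace = TRUE)
  b <- rnorm(n_ind, 0, sigma_b)
  rows <- lapply(seq_len(n_ind), function(i) {
    dur <- seq(0, by = 1.5, length.out = n_vis)
    val <- intercept + offsets[[subgroups[i]]] + slope * dur +
      sex_eff * (sex[i] == "M") + b[i] + rnorm(n_vis, 0, sigma_e)
    data.frame(id = ids[i], duration = dur, bmi = NA_real_,
               hba1c = NA_real_, hdl = NA_real_, c_peptide = NA_real_,
               sbp = NA_real_, dbp = NA_real_,
               creatinine = pmax(val, 0.1), triglycerides = NA_real_,
               total_chol = NA_real_, ldl = NA_real_, atc_codes = "")
  })
  ind <- data.frame(id = ids, sex = sex, age_at_diagnosis = 55,
                    gad_positive = FALSE)
  # baseline indicators vary but are unrelated to the outcome, so the
  # "indicators" predictor set is genuinely irrelevant here
  baseline <- data.frame(id = ids, sex = sex, age = 55 + runif(n_ind, 0, 10),
                         bmi = rnorm(n_ind, 30, 4),
                         hba1c = rnorm(n_ind, 55, 10),
                         c_peptide = rnorm(n_ind, 1.2, 0.3),
                         hdl = rnorm(n_ind, 1.2, 0.2),
                         baseline_duration = 0.2)
  list(cohort = cohort(ind, do.call(rbind, rows)),
       labels = setNames(subgroups, ids),
       baseline = baseline,
       truth = list(offsets = offsets, sigma_b = sigma_b,
                    sigma_e = sigma_e, slope = slope, sex_eff = sex_eff))
}

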