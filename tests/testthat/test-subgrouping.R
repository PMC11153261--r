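make_scaling <- function(location, scale, n = 10) {
  structure(list(M = list(location = location, scale = scale, n = n),
                 F = list(location = location, scale = scale, n = n)),
            class = "scaling_params")
}

test_that("scaling parameters are per-sex sample moments", {
  b <- data.frame(id = c("m1", "m2", "f1", "f2"),
                  sex = c("M", "M", "F", "F"),
                  age = c(50, 60, 55, 65), bmi = c(28, 32, 27, 33),
                  hba1c = c(40, 60, 45, 55), c_peptide = c(0.8, 1.2, 1, 1.4),
                  hdl = c(1.0, 1.4, 1.1, 1.5))
  sc <- compute_scaling(b)
  expect_equal(sc$M$location[["hba1c"]], 50)
  expect_equal(sc$M$scale[["hba1c"]], sqrt(200))

  # z-scoring its own fitting sample gives mean 0, sd 1 per sex
  z <- scale_indicators(b[, INDICATORS], b$sex, sc)
  for (s in c("M", "F")) {
    expect_equal(unname(colMeans(z[b$sex == s, ])), rep(0, 5))
    expect_equal(unname(apply(z[b$sex == s, ], 2, sd)), rep(1, 5))
  }

  # stratification: female parameters ignore male records
  b2 <- rbind(b, data.frame(id = "m3", sex = "M", age = 80, bmi = 40,
                            hba1c = 99, c_peptide = 3, hdl = 2))
  expect_identical(compute_scaling(b2)$F, sc$F)

  b3 <- b
  b3$hdl[b3$sex == "F"] <- 1.2
  expect_error(compute_scaling(b3), "zero variance.*hdl")
  expect_error(compute_scaling(b[1:3, ]), ">= 2 individuals")
})

test_that("scaling round-trips and rejects incomplete input", {
  sc <- make_scaling(
    location = c(age = 60, bmi = 30, hba1c = 55, c_peptide = 1.2, hdl = 1.2),
    scale = c(age = 9, bmi = 4, hba1c = 12, c_peptide = 0.5, hdl = 0.3))
  set.seed(1)
  x <- matrix(runif(50, 0.5, 100), 10, 5, dimnames = list(NULL, INDICATORS))
  z <- scale_indicators(as.data.frame(x), "M", sc)
  back <- unscale_indicators(z, "M", sc)
  expect_equal(unname(back), unname(x), tolerance = 1e-12)
  expect_error(scale_indicators(c(age = 60, bmi = 30), "M", sc), "missing")
})

test_that("subgroup fitting is deterministic and recovers separated blobs", {
  sim <- simulate_cohort(sep_params(800, seed = 21))
  b <- select_baseline(apply_inclusion_criteria(sim$cohort))
  m1 <- fit_subgroups(b, seed = 7)
  m2 <- fit_subgroups(b, seed = 7)
  expect_identical(m1$centres, m2$centres)
  expect_identical(m1$labels, m2$labels)

  named <- name_clusters(m1, table1_centres("DCS"))
  acc <- mean(named$labels == sim$true_labels[names(named$labels)])
  expect_gte(acc, 0.98)

  # pooled centres equal the member-wise arithmetic mean in scaled space
  z <- scale_indicators(b[, INDICATORS], b$sex, m1$scaling)
  for (j in seq_len(5)) {
    expect_equal(unname(m1$centres[j, ]),
                 unname(colMeans(z[m1$labels == j, , drop = FALSE])),
                 tolerance = 1e-10)
  }

  # k-means fixed point: nearest-centre assignment reproduces the partition
  relab <- assign_subgroups(b, named)
  expect_identical(unname(relab), unname(named$labels))

  # duplicating every individual leaves the partition unchanged; centres
  # shift only through the n-1 denominator of the sample-SD scaling
  b_dup <- rbind(b, transform(b, id = paste0(b$id, "_dup")))
  m_dup <- fit_subgroups(b_dup, seed = 7)
  expect_equal(sort(m_dup$centres[, "hba1c"]), sort(m1$centres[, "hba1c"]),
               tolerance = 1e-2)
  named_dup <- name_clusters(m_dup, table1_centres("DCS"))
  expect_identical(unname(named_dup$labels[names(named$labels)]),
                   unname(named$labels))
  expect_error(fit_subgroups(b[1:6, ]), "fewer than k")
})

test_that("centre naming uses exact optimal assignment", {
  sim <- simulate_cohort(sep_params(400, seed = 31))
  b <- select_baseline(apply_inclusion_criteria(sim$cohort))
  m <- fit_subgroups(b, seed = 2)

  # reference = the fitted centres themselves: identity naming, distance 0
  ref <- m$centres
  rownames(ref) <- SUBGROUPS
  named <- name_clusters(m, ref, reference_scale = "scaled")
  expect_identical(named$names, SUBGROUPS)
  expect_equal(named$naming_total_distance, 0)

  # swapping two reference names is recovered as the same swap
  ref_swap <- ref[c(2, 1, 3, 4, 5), ]
  rownames(ref_swap) <- SUBGROUPS
  named_swap <- name_clusters(m, ref_swap, reference_scale = "scaled")
  expect_identical(named_swap$names,
                   c("SIRD", "SIDD", "MOD", "MD", "MDH"))

  expect_error(name_clusters(m, ref[1:4, ]), "exactly 5")

  # random cost matrices: enumeration equals the DFS oracle
  set.seed(99)
  for (r in 1:20) {
    cost <- matrix(runif(25), 5, 5)
    sol <- t2dsubgroups:::optimal_assignment(cost)
    expect_equal(sol$cost, oracle_assignment_cost(cost), tolerance = 1e-12)
  }
})

test_that("nearest-centre assignment is exact, tie-broken and scale-stable", {
  sc <- make_scaling(
    location = c(age = 60, bmi = 31, hba1c = 60, c_peptide = 1.3, hdl = 1.2),
    scale = c(age = 8, bmi = 4.5, hba1c = 15, c_peptide = 0.5, hdl = 0.3))
  centres <- scale_indicators(as.data.frame(table1_centres("DCS")), "M", sc)
  model <- structure(list(scaling = sc, centres = centres, names = SUBGROUPS,
                          k = 5), class = "cluster_model")

  # published SIDD mean vector lands on the SIDD centre at distance 0
  sidd <- table1_centres("DCS")["SIDD", ]
  expect_identical(assign_nearest_centre(sidd, "M", model), "SIDD")
  md <- table1_centres("DCS")["MD", ]
  expect_identical(assign_nearest_centre(md, "F", model), "MD")

  # common positive rescaling of all scaled axes changes nothing
  model2 <- model
  model2$centres <- model$centres * 3
  model2$scaling$M$scale <- model$scaling$M$scale / 3
  model2$scaling$F$scale <- model$scaling$F$scale / 3
  model2$scaling$M$location <- model$scaling$M$location
  set.seed(7)
  for (r in 1:20) {
    x <- sidd * runif(5, 0.7, 1.3)
    expect_identical(assign_nearest_centre(x, "M", model2),
                     assign_nearest_centre(x, "M", model))
  }

  # exact tie: equidistant from two centres resolves by canonical order
  tie_model <- model
  tie_model$centres <- rbind(c(1, 0, 0, 0, 0), c(-1, 0, 0, 0, 0),
                             c(9, 9, 9, 9, 9), c(9, 9, 9, 9, -9),
                             c(9, 9, 9, -9, 9))
  colnames(tie_model$centres) <- INDICATORS
  tie_model$names <- c("MD", "SIRD", "MOD", "SIDD", "MDH")
  origin <- unscale_indicators(setNames(rep(0, 5), INDICATORS), "M", sc)
  expect_identical(assign_nearest_centre(origin, "M", tie_model), "SIRD")
})

test_that("partition agreement matches a direct-summation oracle", {
  x <- c("SIDD", "MD", "MOD", "MDH", "SIRD", "MD")
  rep_id <- compare_partitions(x, x)
  expect_equal(rep_id$accuracy, 1)
  expect_equal(rep_id$kappa, 1)
  expect_true(all(rep_id$per_class$specific_agreement %in% c(1, NaN, NA)))

  # chance-level 2x2: accuracy 1/2, kappa 0
  r <- c("a", "a", "b", "b")
  cand <- c("a", "b", "a", "b")
  rep2 <- compare_partitions(r, cand)
  expect_equal(rep2$accuracy, 0.5)
  expect_equal(rep2$kappa, 0)

  expect_error(compare_partitions(x, x[-1]), "length")
  expect_error(compare_partitions(character(0), character(0)), "empty")

  set.seed(11)
  for (r in 1:50) {
    a <- sample(SUBGROUPS, 200, replace = TRUE)
    b <- sample(SUBGROUPS, 200, replace = TRUE)
    got <- compare_partitions(a, b, levels = SUBGROUPS)
    want <- oracle_agreement(a, b, SUBGROUPS)
    expect_equal(got$kappa, want$kappa, tolerance = 1e-12)
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-12)
    expect_equal(got$per_class$specific_agreement, want$specific_agreement,
                 tolerance = 1e-12)
    # permuting both sequences identically leaves every metric unchanged
    perm <- setNames(sample(SUBGROUPS), SUBGROUPS)
    got_p <- compare_partitions(perm[a], perm[b], levels = SUBGROUPS)
    expect_equal(got_p$kappa, got$kappa, tolerance = 1e-12)
    expect_equal(got_p$accuracy, got$accuracy, tolerance = 1e-12)
  }
})
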