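# Sex-stratified k-means subgrouping of the five baseline clinical
# indicators, centroid naming against reference centres, nearest-centre
# assignment, and multi-class partition agreement.

#' Per-sex z-scoring parameters for the clustering indicators
#'
#' Location (sample mean) and scale (sample SD, denominator n-1) per sex and
#' indicator, computed on the baseline sample. Men and women are scaled
#' separately so that sex-dependent differences in indicator distributions
#' do not drive the clustering.
#'
#' @param baseline baseline table from [select_baseline()]: columns `id`,
#'   `sex` and the five [INDICATORS].
#' @return A `scaling_params` object: per-sex lists with `location` and
#'   `scale` vectors over the indicators, plus per-sex sample sizes.
#' @export
compute_scaling <- function(baseline) {
  stopifnot(all(c("sex", INDICATORS) %in% names(baseline)))
  out <- list()
  for (s in c("M", "F")) {
    sub <- baseline[baseline$sex == s, INDICATORS, drop = FALSE]
    if (nrow(sub) < 2) {
      stop("need >= 2 individuals of sex ", s, " to compute scaling")
    }
    loc <- vapply(sub, mean, numeric(1))
    sc <- vapply(sub, sd, numeric(1))
    zero <- names(sc)[sc == 0]
    if (length(zero)) {
      stop("zero variance in (", s, ", ", paste(zero, collapse = ", "),
           "); cannot scale")
    }
    out[[s]] <- list(location = loc, scale = sc, n = nrow(sub))
  }
  structure(out, class = "scaling_params")
}

#' Scale indicator values into the per-sex z-score space
#'
#' `(value - location) / scale` with the sex-specific parameters, in the
#' fixed component order age, bmi, hba1c, c_peptide, hdl.
#'
#' @param indicators named numeric vector, or data.frame/matrix with the
#'   indicator columns (one row per individual).
#' @param sex `"M"` or `"F"`; scalar or one per row.
#' @param scaling a `scaling_params` object.
#' @return A numeric vector (single individual) or matrix with columns in
#'   indicator order.
#' @export
scale_indicators <- function(indicators, sex, scaling) {
  stopifnot(inherits(scaling, "scaling_params"))
  if (is.null(dim(indicators))) {
    indicators <- as.data.frame(as.list(indicators))
    single <- TRUE
  } else {
    single <- FALSE
  }
  miss <- setdiff(INDICATORS, names(indicators))
  if (length(miss)) {
    stop("missing indicator component(s): ", paste(miss, collapse = ", "))
  }
  x <- as.matrix(indicators[, INDICATORS, drop = FALSE])
  if (anyNA(x)) stop("missing indicator value(s); complete cases required")
  sex <- rep_len(sex, nrow(x))
  z <- matrix(NA_real_, nrow(x), 5, dimnames = list(NULL, INDICATORS))
  for (s in c("M", "F")) {
    i <- which(sex == s)
    if (!length(i)) next
    p <- scaling[[s]]
    z[i, ] <- sweep(sweep(x[i, , drop = FALSE], 2, p$location), 2,
                    p$scale, "/")
  }
  if (single) z[1, ] else z
}

#' Invert the per-sex z-scoring
#'
#' @param z scaled vector or matrix as produced by [scale_indicators()].
#' @param sex `"M"` or `"F"`; scalar or one per row.
#' @param scaling a `scaling_params` object.
#' @return Raw-unit values.
#' @export
unscale_indicators <- function(z, sex, scaling) {
  stopifnot(inherits(scaling, "scaling_params"))
  single <- is.null(dim(z))
  if (single) z <- matrix(z, 1, dimnames = list(NULL, names(z)))
  z <- z[, INDICATORS, drop = FALSE]
  sex <- rep_len(sex, nrow(z))
  x <- z
  for (s in c("M", "F")) {
    i <- which(sex == s)
    if (!length(i)) next
    p <- scaling[[s]]
    x[i, ] <- sweep(sweep(z[i, , drop = FALSE], 2, p$scale, "*"), 2,
                    p$location, "+")
  }
  if (single) x[1, ] else x
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (p in sub) {
      k <- k + 1L
      rest <- seq_len(n)[-i]
      out[[k]] <- c(i, rest[p])
    }
  }
  out
}

# exact minimum-cost one-to-one assignment by exhaustive enumeration;
# at k = 5 there are only 120 permutations, so enumeration is exact and
# cheap, and cannot be trapped the way greedy matching can on close centres
optimal_assignment <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost))
  perms <- all_permutations(nrow(cost))
  best <- NULL
  best_cost <- Inf
  for (p in perms) {
    cc <- sum(cost[cbind(seq_along(p), p)])
    if (cc < best_cost) {
      best_cost <- cc
      best <- p
    }
  }
  list(assignment = best, cost = best_cost)
}

#' Fit the five subgroups by sex-stratified k-means
#'
#' Runs k-means (k = 5) separately on the male and female strata in the
#' per-sex scaled indicator space, matches female clusters to male clusters
#' by minimal total Euclidean centroid distance under an exact one-to-one
#' assignment, and pools each matched pair: the pooled centre is the
#' arithmetic mean of the scaled indicator vectors of all members of the
#' pair, both sexes.
#'
#' @param baseline baseline table ([select_baseline()]).
#' @param k number of clusters; fixed at 5 in this analysis.
#' @param seed RNG seed controlling the k-means restarts.
#' @param n_init number of random restarts.
#' @return An (unnamed) `cluster_model`: scaling parameters, `k` pooled
#'   centres in scaled space, per-individual cluster indices (`labels`,
#'   named by id), per-cluster sizes, total within-cluster sum of squares
#'   and fit metadata. Name the centres with [name_clusters()].
#' @export
fit_subgroups <- function(baseline, k = 5, seed = 1L, n_init = 25) {
  stopifnot(all(c("id", "sex", INDICATORS) %in% names(baseline)))
  scaling <- compute_scaling(baseline)
  set.seed(seed)
  km <- list()
  Z <- list()
  idx <- list()
  for (s in c("M", "F")) {
    i <- which(baseline$sex == s)
    if (length(i) < k) {
      stop("sex stratum ", s, " has fewer than k = ", k, " individuals")
    }
    Zi <- scale_indicators(baseline[i, INDICATORS], s, scaling)
    fit <- NULL
    for (try in 1:5) {
      fit <- tryCatch(
        kmeans(Zi, centers = k, nstart = n_init, iter.max = 100),
        error = function(e) NULL)
      if (!is.null(fit) && all(fit$size > 0)) break
      message("k-means re-run for stratum ", s, " (attempt ", try + 1, ")")
    }
    if (is.null(fit)) stop("k-means failed for sex stratum ", s)
    km[[s]] <- fit
    Z[[s]] <- Zi
    idx[[s]] <- i
  }
  # match female clusters to male clusters (exact assignment on centre
  # distances), then pool members of each matched pair
  D <- matrix(NA_real_, k, k)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      D[a, b] <- sqrt(sum((km$M$centers[a, ] - km$F$centers[b, ])^2))
    }
  }
  match_f <- optimal_assignment(D)$assignment
  centres <- matrix(NA_real_, k, 5, dimnames = list(NULL, INDICATORS))
  sizes <- integer(k)
  labels <- integer(nrow(baseline))
  for (j in seq_len(k)) {
    m_members <- km$M$cluster == j
    f_members <- km$F$cluster == match_f[j]
    pooled <- rbind(Z$M[m_members, , drop = FALSE],
                    Z$F[f_members, , drop = FALSE])
    centres[j, ] <- colMeans(pooled)
    sizes[j] <- nrow(pooled)
    labels[idx$M[m_members]] <- j
    labels[idx$F[f_members]] <- j
  }
  structure(list(
    scaling = scaling,
    centres = centres,
    names = NULL,
    k = k,
    labels = setNames(labels, baseline$id),
    sizes = sizes,
    inertia = km$M$tot.withinss + km$F$tot.withinss,
    seed = seed,
    n_init = n_init), class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> k =", x$k,
      if (is.null(x$names)) "(unnamed)" else "(named)", "\n")
  cm <- x$centres
  if (!is.null(x$names)) rownames(cm) <- x$names
  print(round(cm, 3))
  cat("cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Published per-subgroup baseline indicator means
#'
#' The per-subgroup baseline means of the five clustering indicators in the
#' chosen registry style, usable as raw-unit reference centres for
#' [name_clusters()].
#'
#' @param cohort_style `"DCS"` or `"GoDARTS"`.
#' @return 5 x 5 matrix, rows named by subgroup, columns the indicators.
#' @export
table1_centres <- function(cohort_style = c("DCS", "GoDARTS")) {
  cohort_style <- match.arg(cohort_style)
  m <- if (cohort_style == "DCS") .TAB_DCS_MEAN else .TAB_GODARTS_MEAN
  m[SUBGROUPS, INDICATORS]
}

#' Name fitted cluster centres against reference centres
#'
#' Assigns the five subgroup names to the fitted centres by the one-to-one
#' assignment minimising the total Euclidean distance between fitted and
#' reference centres (exact minimisation over all 120 permutations, never
#' greedy). Raw-unit references are scaled into the model's space with the
#' model's own per-sex scaling parameters, combined across sexes weighted by
#' stratum size.
#'
#' @param model an unnamed `cluster_model`.
#' @param reference_centres 5-row matrix with rownames giving the subgroup
#'   names; columns must cover the [INDICATORS]. Defaults to the published
#'   DCS baseline means.
#' @param reference_scale `"raw"` if the reference is in indicator units,
#'   `"scaled"` if already in the model's scaled space.
#' @return The model with `names` set (centre row i is called
#'   `model$names[i]`), `labels` converted to subgroup names, and the audit
#'   distance matrix in `naming_distance`.
#' @export
name_clusters <- function(model, reference_centres = table1_centres("DCS"),
                          reference_scale = c("raw", "scaled")) {
  stopifnot(inherits(model, "cluster_model"))
  reference_scale <- match.arg(reference_scale)
  ref <- as.matrix(reference_centres)
  if (nrow(ref) != model$k) {
    stop("reference must have exactly ", model$k, " centres")
  }
  if (is.null(rownames(ref))) stop("reference centres must be named")
  ref <- ref[, INDICATORS, drop = FALSE]
  ref_names <- rownames(ref)
  if (reference_scale == "raw") {
    zm <- scale_indicators(as.data.frame(ref), "M", model$scaling)
    zf <- scale_indicators(as.data.frame(ref), "F", model$scaling)
    nm <- model$scaling$M$n
    nf <- model$scaling$F$n
    ref <- (nm * zm + nf * zf) / (nm + nf)
  }
  D <- matrix(NA_real_, model$k, model$k,
              dimnames = list(NULL, ref_names))
  for (i in seq_len(model$k)) {
    for (j in seq_len(model$k)) {
      D[i, j] <- sqrt(sum((model$centres[i, ] - ref[j, ])^2))
    }
  }
  sol <- optimal_assignment(D)
  model$names <- ref_names[sol$assignment]
  model$naming_distance <- D
  model$naming_total_distance <- sol$cost
  rownames(model$centres) <- model$names
  if (!is.null(model$labels) && is.numeric(model$labels)) {
    model$labels <- setNames(model$names[model$labels], names(model$labels))
  }
  model
}

#' Assign indicators to the nearest subgroup centre
#'
#' Scales the indicator vector with the model's sex-specific parameters and
#' returns the name of the Euclidean-nearest centre. Ties are broken by the
#' fixed canonical order SIDD < SIRD < MOD < MD < MDH.
#'
#' @param indicators named numeric vector with the five [INDICATORS].
#' @param sex `"M"` or `"F"`.
#' @param model a named `cluster_model`.
#' @return Subgroup name (character scalar).
#' @export
assign_nearest_centre <- function(indicators, sex, model) {
  stopifnot(inherits(model, "cluster_model"))
  if (is.null(model$names)) stop("model must be named first (name_clusters)")
  z <- scale_indicators(indicators, sex, model$scaling)
  d <- sqrt(colSums((t(model$centres) - z)^2))
  nearest_name(d, model$names)
}

nearest_name <- function(d, names) {
  at_min <- which(d == min(d))
  if (length(at_min) > 1) {
    ord <- match(names[at_min], SUBGROUPS)
    at_min <- at_min[which.min(ord)]
  }
  names[at_min]
}

#' Nearest-centre assignment for a whole baseline-style table
#'
#' Vectorised [assign_nearest_centre()] over the rows of a table with `id`,
#' `sex` and the indicator columns.
#'
#' @param tab data.frame with `id`, `sex` and the [INDICATORS].
#' @param model a named `cluster_model`.
#' @return Character vector of subgroup names, named by `id`.
#' @export
assign_subgroups <- function(tab, model) {
  stopifnot(inherits(model, "cluster_model"))
  if (is.null(model$names)) stop("model must be named first (name_clusters)")
  z <- scale_indicators(tab[, INDICATORS], tab$sex, model$scaling)
  out <- character(nrow(z))
  ctr <- t(model$centres)
  for (i in seq_len(nrow(z))) {
    d <- sqrt(colSums((ctr - z[i, ])^2))
    out[i] <- nearest_name(d, model$names)
  }
  setNames(out, tab$id)
}

#' Multi-class agreement between two partitions
#'
#' Confusion matrix (reference x candidate) with overall accuracy and its
#' exact (Clopper-Pearson) 95\% CI, Cohen's kappa, and per-class
#' sensitivity, specificity and (positive) specific agreement
#' `2 n_cc / (row_c + col_c)`.
#'
#' @param reference,candidate equal-length label vectors over the same
#'   individuals (compared positionally).
#' @param levels class levels; defaults to the canonical subgroup order,
#'   extended by any other labels present.
#' @return An `agreement_report` object.
#' @export
compare_partitions <- function(reference, candidate, levels = NULL) {
  if (length(reference) != length(candidate)) {
    stop("label sequences differ in length")
  }
  if (length(reference) == 0) stop("empty label sequences")
  if (is.null(levels)) {
    seen <- unique(c(as.character(reference), as.character(candidate)))
    levels <- c(intersect(SUBGROUPS, seen), sort(setdiff(seen, SUBGROUPS)))
  }
  f_ref <- factor(as.character(reference), levels = levels)
  f_can <- factor(as.character(candidate), levels = levels)
  if (anyNA(f_ref) || anyNA(f_can)) stop("labels outside the given levels")
  conf <- table(reference = f_ref, candidate = f_can)
  n <- sum(conf)
  agree <- sum(diag(conf))
  accuracy <- agree / n
  ci <- as.numeric(binom.test(agree, n)$conf.int)
  rows <- rowSums(conf)
  cols <- colSums(conf)
  p_o <- accuracy
  p_e <- sum(rows * cols) / n^2
  kappa <- if (p_e == 1) 1 else (p_o - p_e) / (1 - p_e)
  per_class <- data.frame(
    class = levels,
    sensitivity = ifelse(rows > 0, diag(conf) / rows, NA_real_),
    specificity = (n - rows - cols + diag(conf)) / (n - rows),
    specific_agreement = ifelse(rows + cols > 0,
                                2 * diag(conf) / (rows + cols), NA_real_),
    row.names = NULL)
  structure(list(confusion = conf, n = n, accuracy = accuracy,
                 accuracy_ci = ci, kappa = kappa, per_class = per_class),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report> n =", x$n, "\n")
  cat(sprintf("accuracy %.4f (95%% CI %.4f, %.4f)   kappa %.4f\n",
              x$accuracy, x$accuracy_ci[1], x$accuracy_ci[2], x$kappa))
  print(x$confusion)
  print(x$per_class, digits = 3)
  invisible(x)
}
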