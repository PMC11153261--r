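# Windowed re-assessment of subgroup membership over follow-up: in-window
# indicator summaries, de novo re-clustering vs nearest-centre reallocation,
# agreement with the baseline partition, transition trajectories, and the
# severe/mild movement dichotomy.

#' Follow-up window specification
#'
#' Half-open duration intervals `[a, b)` on the diabetes-duration axis.
#' The default is the four 2-year windows `[0,2), [2,4), [4,6), [6,8)`.
#'
#' @param breaks increasing numeric vector of window boundaries.
#' @return A `window_spec`: named list of `c(lower, upper)` pairs; names are
#'   `"[a,b)"` labels.
#' @export
window_spec <- function(breaks = c(0, 2, 4, 6, 8)) {
  if (length(breaks) < 2 || any(diff(breaks) <= 0)) {
    stop("breaks must be strictly increasing with >= 2 values")
  }
  out <- lapply(seq_len(length(breaks) - 1),
                function(i) c(breaks[i], breaks[i + 1]))
  names(out) <- vapply(out, function(w) sprintf("[%g,%g)", w[1], w[2]),
                       character(1))
  structure(out, class = "window_spec")
}

#' In-window clustering indicators per individual
#'
#' For every individual and window with at least one visit: BMI, HbA1c and
#' HDL are the means of the available in-window values; C-peptide is carried
#' forward from baseline (it is treated as constant over follow-up, since
#' registries rarely re-assay it); age is the age at the first in-window
#' visit. Individuals lacking any required component in a window are dropped
#' from that window with a logged count.
#'
#' @param x a `t2d_cohort`.
#' @param windows a `window_spec`.
#' @param baseline baseline table from [select_baseline()] (source of the
#'   carried-forward C-peptide).
#' @param carry_forward_cpeptide if `FALSE`, use the in-window mean of
#'   measured C-peptide where available, falling back to baseline.
#' @return Long data.frame: `id, sex, window, age, bmi, hba1c, c_peptide,
#'   hdl`.
#' @export
window_indicators <- function(x, windows = window_spec(), baseline,
                              carry_forward_cpeptide = TRUE) {
  validate_cohort(x)
  stopifnot(inherits(windows, "window_spec"))
  ind <- x$individuals
  vis <- x$visits
  base_cpep <- setNames(baseline$c_peptide, baseline$id)
  rows <- list()
  for (wl in names(windows)) {
    w <- windows[[wl]]
    inw <- vis[vis$duration >= w[1] & vis$duration < w[2], , drop = FALSE]
    if (!nrow(inw)) next
    dropped <- 0L
    for (id in unique(inw$id)) {
      v <- inw[inw$id == id, , drop = FALSE]
      mean_or_na <- function(col) {
        val <- v[[col]][!is.na(v[[col]])]
        if (length(val)) mean(val) else NA_real_
      }
      cp <- if (carry_forward_cpeptide) {
        unname(base_cpep[id])
      } else {
        cpw <- mean_or_na("c_peptide")
        if (is.na(cpw)) unname(base_cpep[id]) else cpw
      }
      if (is.null(cp) || length(cp) == 0) cp <- NA_real_
      first_d <- min(v$duration)
      m <- match(id, ind$id)
      row <- data.frame(id = id, sex = ind$sex[m], window = wl,
                        age = ind$age_at_diagnosis[m] + first_d,
                        bmi = mean_or_na("bmi"),
                        hba1c = mean_or_na("hba1c"),
                        c_peptide = cp,
                        hdl = mean_or_na("hdl"))
      if (anyNA(row[, INDICATORS])) {
        dropped <- dropped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- row
    }
    if (dropped > 0) {
      message(dropped, " individual(s) dropped from window ", wl,
              " for incomplete indicators")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Windowed de novo re-clustering
#'
#' Per window: re-scale within the window, re-fit sex-stratified k-means
#' with [fit_subgroups()], and name the shifted centres against the baseline
#' model's centres by exact optimal assignment (consistency is defined
#' against the baseline subgroups).
#'
#' @param window_table output of [window_indicators()].
#' @param baseline_model named `cluster_model` fitted at baseline.
#' @param seed RNG seed (a distinct sub-seed is used per window).
#' @return A `reallocation` object: per-window label vectors (named by id)
#'   and the per-window shifted models.
#' @export
denovo_reallocate <- function(window_table, baseline_model, seed = 1L) {
  stopifnot(inherits(baseline_model, "cluster_model"))
  if (is.null(baseline_model$names)) stop("baseline model must be named")
  labels <- list()
  models <- list()
  wls <- unique(window_table$window)
  ref <- baseline_model$centres  # already scaled, rownames = names
  for (j in seq_along(wls)) {
    wl <- wls[j]
    tab <- window_table[window_table$window == wl, , drop = FALSE]
    m <- tryCatch(
      fit_subgroups(tab, k = baseline_model$k, seed = seed + j,
                    n_init = baseline_model$n_init),
      error = function(e) {
        warning("window ", wl, " skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(m)) next
    m <- name_clusters(m, ref, reference_scale = "scaled")
    labels[[wl]] <- m$labels
    models[[wl]] <- m
  }
  structure(list(labels = labels, models = models, method = "denovo"),
            class = "reallocation")
}

#' Windowed centre-based reallocation
#'
#' Per window, assigns each individual to the subgroup with the lowest
#' Euclidean distance to the cluster centres identified at baseline, using
#' the frozen baseline scaling. No re-fitting, no re-scaling, no randomness.
#'
#' @param window_table output of [window_indicators()].
#' @param baseline_model named `cluster_model` fitted at baseline.
#' @return A `reallocation` object with per-window label vectors.
#' @export
centre_reallocate <- function(window_table, baseline_model) {
  stopifnot(inherits(baseline_model, "cluster_model"))
  if (is.null(baseline_model$names)) stop("baseline model must be named")
  labels <- list()
  for (wl in unique(window_table$window)) {
    tab <- window_table[window_table$window == wl, , drop = FALSE]
    labels[[wl]] <- assign_subgroups(tab, baseline_model)
  }
  structure(list(labels = labels, models = NULL, method = "centre"),
            class = "reallocation")
}

#' @export
print.reallocation <- function(x, ...) {
  cat("<reallocation> method:", x$method, " windows:",
      paste(names(x$labels), collapse = " "), "\n")
  invisible(x)
}

as_label_list <- function(window_labels) {
  if (inherits(window_labels, "reallocation")) window_labels$labels
  else window_labels
}

#' Per-window agreement with the baseline partition
#'
#' Runs [compare_partitions()] per window with the baseline labels as
#' reference (restricted to the individuals present in both), and reports
#' the relative accuracy change between the first and last window.
#'
#' @param baseline_labels named character vector of baseline subgroups.
#' @param window_labels a `reallocation` or a named list of per-window label
#'   vectors (named by id).
#' @return list with `reports` (per-window `agreement_report`s), `accuracy`
#'   (named numeric) and `trend` (relative change last vs first window).
#' @export
consistency_report <- function(baseline_labels, window_labels) {
  wl <- as_label_list(window_labels)
  reports <- list()
  acc <- numeric(0)
  for (w in names(wl)) {
    ids <- intersect(names(baseline_labels), names(wl[[w]]))
    if (!length(ids)) stop("window ", w, " shares no individuals with baseline")
    rep_w <- compare_partitions(baseline_labels[ids], wl[[w]][ids])
    reports[[w]] <- rep_w
    acc[w] <- rep_w$accuracy
  }
  trend <- (acc[length(acc)] - acc[1]) / acc[1]
  list(reports = reports, accuracy = acc, trend = unname(trend))
}

#' Transition trajectories across follow-up windows
#'
#' Only individuals observed in all windows enter. Counts every distinct
#' label sequence, ranks the top `top_n` (ties broken lexicographically),
#' and reports the per-subgroup stay fraction: the fraction of
#' complete-sequence individuals starting in a subgroup whose sequence is
#' constant.
#'
#' @param window_labels a `reallocation` or named list of per-window label
#'   vectors.
#' @param top_n how many top trajectories to rank.
#' @return A `transition_table`: trajectory counts, the top-n table, number
#'   of complete sequences and the stay fractions.
#' @export
enumerate_transitions <- function(window_labels, top_n = 10) {
  wl <- as_label_list(window_labels)
  ids <- Reduce(intersect, lapply(wl, names))
  if (!length(ids)) stop("no individual has labels in all windows")
  seqs <- vapply(ids, function(id) {
    paste(vapply(wl, function(l) unname(l[id]), character(1)),
          collapse = "->")
  }, character(1))
  tab <- table(seqs)
  counts <- data.frame(trajectory = names(tab), count = as.integer(tab),
                       row.names = NULL)
  counts <- counts[order(-counts$count, counts$trajectory), , drop = FALSE]
  rownames(counts) <- NULL
  first <- vapply(ids, function(id) unname(wl[[1]][id]), character(1))
  constant <- vapply(ids, function(id) {
    l <- vapply(wl, function(x) unname(x[id]), character(1))
    all(l == l[1])
  }, logical(1))
  stay <- vapply(SUBGROUPS, function(s) {
    i <- first == s
    if (!any(i)) return(NA_real_)
    mean(constant[i])
  }, numeric(1))
  structure(list(counts = counts,
                 top = head(counts, top_n),
                 n_complete = length(ids),
                 stay_fraction = stay),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat("<transition_table> complete sequences:", x$n_complete, "\n")
  print(x$top)
  cat("stay fractions:\n")
  print(round(x$stay_fraction, 3))
  invisible(x)
}

#' Severe/mild movement groups
#'
#' Classifies each individual's movement between baseline and a follow-up
#' window into one of `severe->severe`, `severe->mild`, `mild->severe`,
#' `mild->mild`, where the severe subgroups are SIDD and SIRD and the mild
#' subgroups are MOD, MD and MDH. The result is a 2 x 2 stratification
#' usable as a covariate in the outcome models.
#'
#' @param baseline_labels named character vector of baseline subgroups.
#' @param window_labels named character vector of follow-up subgroups
#'   (typically the first re-assessment window).
#' @return Character vector of movement groups, named by id, over the
#'   individuals covered by both inputs.
#' @export
severe_mild_movement <- function(baseline_labels, window_labels) {
  severity <- function(l) {
    if (any(!l %in% SUBGROUPS)) {
      stop("unknown subgroup label(s): ",
           paste(setdiff(l, SUBGROUPS), collapse = ", "))
    }
    ifelse(l %in% c("SIDD", "SIRD"), "severe", "mild")
  }
  ids <- intersect(names(baseline_labels), names(window_labels))
  from <- severity(baseline_labels[ids])
  to <- severity(window_labels[ids])
  setNames(paste0(from, "->", to), ids)
}
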