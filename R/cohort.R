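# Longitudinal cohort container: per-individual baseline record, per-visit
# clinical measurements + active ATC codes, and first-event outcome records,
# all on the diabetes-duration time axis (fractional years, 0 at diagnosis).

#' Construct a longitudinal diabetes cohort
#'
#' Bundles the three registry-style tables into a validated `t2d_cohort`
#' object. All times are diabetes duration in fractional years (0 at
#' diagnosis); follow-up windows elsewhere in the package are half-open
#' `[a, b)` intervals on this axis.
#'
#' @param individuals data.frame with columns `id`, `sex` (`"M"`/`"F"`),
#'   `age_at_diagnosis` (years, > 0), `gad_positive` (logical; `NA` allowed).
#' @param visits data.frame with columns `id`, `duration` (years since
#'   diagnosis, >= 0) and the measurement columns in [MEASUREMENTS] (missing
#'   values as `NA`, present values strictly positive), plus `atc_codes`
#'   (semicolon-joined ATC code string, `""` for none).
#' @param events data.frame with columns `id`, `outcome` (one of
#'   [OUTCOMES]), `time` (years since diagnosis, > 0) and `observed`
#'   (logical: event vs right-censoring). At most one row per
#'   (individual, outcome): first events only.
#' @param name cohort label stored in the metadata.
#'
#' @return An object of class `t2d_cohort`: a list with elements
#'   `individuals`, `visits`, `events` and `metadata`.
#' @export
cohort <- function(individuals, visits = NULL, events = NULL, name = "cohort") {
  if (is.null(visits)) {
    visits <- empty_visits()
  }
  if (is.null(events)) {
    events <- empty_events()
  }
  individuals$id <- as.character(individuals$id)
  visits$id <- as.character(visits$id)
  if (nrow(events)) events$id <- as.character(events$id)
  if (!"atc_codes" %in% names(visits)) visits$atc_codes <- ""
  visits$atc_codes[is.na(visits$atc_codes)] <- ""
  x <- structure(
    list(individuals = individuals, visits = visits, events = events,
         metadata = list(name = name,
                         time_axis = "years since diabetes diagnosis")),
    class = "t2d_cohort")
  validate_cohort(x)
  x
}

empty_visits <- function() {
  cols <- c("id", "duration", MEASUREMENTS, "atc_codes")
  v <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  v$id <- character(0)
  v$atc_codes <- character(0)
  v
}

empty_events <- function() {
  data.frame(id = character(0), outcome = character(0), time = numeric(0),
             observed = logical(0))
}

#' Validate a cohort's invariants
#'
#' Checks id uniqueness and referential integrity, positivity of ages,
#' measurements and event times, and the first-events-only rule (at most one
#' record per individual and outcome).
#'
#' @param x a `t2d_cohort`.
#' @return `x`, invisibly; stops with an informative error on violation.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "t2d_cohort"))
  ind <- x$individuals
  need <- c("id", "sex", "age_at_diagnosis", "gad_positive")
  miss <- setdiff(need, names(ind))
  if (length(miss)) {
    stop("individuals table lacks mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  if (anyDuplicated(ind$id)) {
    stop("duplicate individual id(s): ",
         paste(unique(ind$id[duplicated(ind$id)]), collapse = ", "))
  }
  if (!all(ind$sex %in% c("M", "F"))) {
    stop("sex must be 'M' or 'F'")
  }
  if (any(!is.na(ind$age_at_diagnosis) & ind$age_at_diagnosis <= 0)) {
    stop("age_at_diagnosis must be > 0")
  }
  vis <- x$visits
  need <- c("id", "duration", "atc_codes")
  miss <- setdiff(c(need, MEASUREMENTS), names(vis))
  if (length(miss)) {
    stop("visits table lacks mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(vis)) {
    if (any(!is.finite(vis$duration)) || any(vis$duration < 0)) {
      stop("visit duration must be finite and >= 0")
    }
    bad <- setdiff(unique(vis$id), ind$id)
    if (length(bad)) {
      stop("visits reference unknown individual(s): ",
           paste(head(bad, 5), collapse = ", "))
    }
    for (m in MEASUREMENTS) {
      v <- vis[[m]]
      if (any(!is.na(v) & (!is.finite(v) | v <= 0))) {
        stop("measurement '", m, "' must be strictly positive where present")
      }
    }
  }
  ev <- x$events
  miss <- setdiff(c("id", "outcome", "time", "observed"), names(ev))
  if (length(miss)) {
    stop("events table lacks mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(ev)) {
    if (!all(ev$outcome %in% OUTCOMES)) {
      stop("unknown outcome label(s): ",
           paste(setdiff(unique(ev$outcome), OUTCOMES), collapse = ", "))
    }
    if (any(!is.finite(ev$time)) || any(ev$time <= 0)) {
      stop("event time must be finite and > 0")
    }
    bad <- setdiff(unique(ev$id), ind$id)
    if (length(bad)) {
      stop("events reference unknown individual(s): ",
           paste(head(bad, 5), collapse = ", "))
    }
    key <- paste(ev$id, ev$outcome)
    if (anyDuplicated(key)) {
      stop("duplicate (individual, outcome) event record(s): ",
           paste(unique(key[duplicated(key)]), collapse = ", "),
           " (first events only)")
    }
  }
  invisible(x)
}

#' @export
print.t2d_cohort <- function(x, ...) {
  cat("<t2d_cohort> ", x$metadata$name, "\n", sep = "")
  cat("  individuals: ", nrow(x$individuals),
      "  visits: ", nrow(x$visits),
      "  event records: ", nrow(x$events), "\n", sep = "")
  if (nrow(x$visits)) {
    cat("  duration range: [",
        round(min(x$visits$duration), 2), ", ",
        round(max(x$visits$duration), 2), "] years\n", sep = "")
  }
  invisible(x)
}

fmt_num <- function(x) {
  # full-precision decimal text so the read/write round trip is bit-identical
  out <- ifelse(is.na(x), "", sprintf("%.17g", x))
  out
}

#' Write a cohort as three delimited tables
#'
#' Emits `individuals.csv`, `visits.csv` and `events.csv` (comma-delimited
#' UTF-8, one header row) into `directory`. Numeric cells are written at full
#' precision so that [read_cohort()] on the output reproduces the cohort
#' bit-identically; missing measurements are empty cells, never sentinel
#' numbers.
#'
#' @param x a valid `t2d_cohort`.
#' @param directory output directory, created if needed.
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(x, directory) {
  validate_cohort(x)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) {
    stop("cannot create directory: ", directory)
  }
  ind <- x$individuals
  ind_out <- data.frame(id = ind$id, sex = ind$sex,
                        age_at_diagnosis = fmt_num(ind$age_at_diagnosis),
                        gad_positive = ifelse(is.na(ind$gad_positive), "",
                                              as.integer(ind$gad_positive)))
  vis <- x$visits
  vis_out <- data.frame(id = vis$id, duration = fmt_num(vis$duration))
  for (m in MEASUREMENTS) vis_out[[m]] <- fmt_num(vis[[m]])
  vis_out$atc_codes <- vis$atc_codes
  ev <- x$events
  ev_out <- data.frame(id = ev$id, outcome = ev$outcome,
                       time = fmt_num(ev$time),
                       observed = as.integer(ev$observed))
  paths <- file.path(directory, c("individuals.csv", "visits.csv",
                                  "events.csv"))
  write.csv(ind_out, paths[1], row.names = FALSE, quote = FALSE, na = "")
  write.csv(vis_out, paths[2], row.names = FALSE, quote = FALSE, na = "")
  write.csv(ev_out, paths[3], row.names = FALSE, quote = FALSE, na = "")
  invisible(paths)
}

read_table_checked <- function(path, mandatory) {
  tab <- read.csv(path, colClasses = "character", check.names = FALSE)
  miss <- setdiff(mandatory, names(tab))
  if (length(miss)) {
    stop("table ", basename(path), " lacks mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  tab
}

num_col <- function(x, what, log_env = NULL) {
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  n_bad <- sum(is.na(out) & !is.na(x))
  if (n_bad > 0) {
    message(n_bad, " unparseable value(s) in column '", what,
            "' treated as missing")
  }
  out
}

#' Read a cohort from three delimited tables
#'
#' Column schemas: individuals `id, sex, age_at_diagnosis, gad_positive`
#' (sex in M/F, gad_positive in 0/1); visits `id, duration,` the
#' [MEASUREMENTS] columns, `atc_codes` (semicolon-joined, empty allowed);
#' events `id, outcome, time, observed`. Unparseable measurement cells become
#' missing values with a logged count; schema violations raise errors naming
#' the offending column.
#'
#' @param visits_path,events_path,individuals_path paths to the three CSVs.
#' @param name cohort label.
#' @return A validated `t2d_cohort`.
#' @export
read_cohort <- function(visits_path, events_path, individuals_path,
                        name = "cohort") {
  ind <- read_table_checked(individuals_path,
                            c("id", "sex", "age_at_diagnosis", "gad_positive"))
  individuals <- data.frame(
    id = ind$id, sex = ind$sex,
    age_at_diagnosis = num_col(ind$age_at_diagnosis, "age_at_diagnosis"),
    gad_positive = as.logical(num_col(ind$gad_positive, "gad_positive")))
  vis <- read_table_checked(visits_path,
                            c("id", "duration", MEASUREMENTS, "atc_codes"))
  visits <- data.frame(id = vis$id,
                       duration = num_col(vis$duration, "duration"))
  for (m in MEASUREMENTS) visits[[m]] <- num_col(vis[[m]], m)
  visits$atc_codes <- vis$atc_codes
  ev <- read_table_checked(events_path, c("id", "outcome", "time", "observed"))
  events <- data.frame(id = ev$id, outcome = ev$outcome,
                       time = num_col(ev$time, "time"),
                       observed = as.logical(num_col(ev$observed, "observed")))
  cohort(individuals, visits, events, name = name)
}

visit_has_indicators <- function(visits) {
  # age is derived from age_at_diagnosis + duration, so completeness of the
  # five clustering indicators at a visit reduces to the four measured ones
  !is.na(visits$bmi) & !is.na(visits$hba1c) &
    !is.na(visits$hdl) & !is.na(visits$c_peptide)
}

#' Apply the study inclusion criteria
#'
#' Retains individuals with diagnosis age >= `min_diagnosis_age`, GAD
#' negativity, and at least one visit within `max_baseline_duration` years of
#' diagnosis carrying all five clustering indicators. Missing GAD status is
#' treated as exclusion unless `missing_gad_as_negative = TRUE`.
#'
#' @param x a `t2d_cohort`.
#' @param max_baseline_duration window (years) in which a complete-indicator
#'   visit must exist. Default 2.
#' @param min_diagnosis_age minimum age at diagnosis. Default 35; the
#'   boundary is inclusive (`>=`).
#' @param missing_gad_as_negative treat missing GAD status as negative.
#' @return A new `t2d_cohort` restricted to the included individuals, with a
#'   per-criterion exclusion count in `attr(., "exclusions")` (criteria
#'   applied in order age, gad, no_baseline).
#' @export
apply_inclusion_criteria <- function(x, max_baseline_duration = 2.0,
                                     min_diagnosis_age = 35,
                                     missing_gad_as_negative = FALSE) {
  validate_cohort(x)
  ind <- x$individuals
  keep_age <- !is.na(ind$age_at_diagnosis) &
    ind$age_at_diagnosis >= min_diagnosis_age
  gad <- ind$gad_positive
  keep_gad <- if (missing_gad_as_negative) {
    is.na(gad) | !gad
  } else {
    !is.na(gad) & !gad
  }
  vis <- x$visits
  ok <- vis$duration <= max_baseline_duration & visit_has_indicators(vis)
  has_baseline <- ind$id %in% unique(vis$id[ok])
  excl <- c(age = sum(!keep_age),
            gad = sum(keep_age & !keep_gad),
            no_baseline = sum(keep_age & keep_gad & !has_baseline))
  keep <- keep_age & keep_gad & has_baseline
  ids <- ind$id[keep]
  out <- structure(
    list(individuals = ind[keep, , drop = FALSE],
         visits = vis[vis$id %in% ids, , drop = FALSE],
         events = x$events[x$events$id %in% ids, , drop = FALSE],
         metadata = x$metadata),
    class = "t2d_cohort")
  rownames(out$individuals) <- NULL
  rownames(out$visits) <- NULL
  rownames(out$events) <- NULL
  attr(out, "exclusions") <- excl
  out
}

#' Select the baseline observation per individual
#'
#' The baseline is the complete-indicator visit nearest to diabetes diagnosis
#' (smallest duration); ties on duration keep the first record in input order
#' with a warning. Age at baseline is age at diagnosis plus the baseline
#' duration.
#'
#' @param x a `t2d_cohort`, normally after [apply_inclusion_criteria()].
#' @return data.frame with one row per individual that has a qualifying
#'   visit: `id, sex, age, bmi, hba1c, c_peptide, hdl, baseline_duration`.
#'   Individuals without any complete-indicator visit are dropped with a
#'   message listing their ids.
#' @export
select_baseline <- function(x) {
  validate_cohort(x)
  vis <- x$visits
  ok <- visit_has_indicators(vis)
  vis <- vis[ok, , drop = FALSE]
  rows <- integer(0)
  tied <- character(0)
  idx <- split(seq_len(nrow(vis)), vis$id)
  for (id in unique(x$individuals$id)) {
    i <- idx[[id]]
    if (is.null(i)) next
    d <- vis$duration[i]
    at_min <- i[d == min(d)]
    if (length(at_min) > 1) tied <- c(tied, id)
    rows <- c(rows, at_min[1])
  }
  if (length(tied)) {
    warning("baseline duration tie for individual(s) ",
            paste(tied, collapse = ", "), "; kept first record in input order")
  }
  missing_ids <- setdiff(x$individuals$id, vis$id)
  if (length(missing_ids)) {
    message(length(missing_ids),
            " individual(s) without a complete-indicator visit dropped: ",
            paste(head(missing_ids, 10), collapse = ", "))
  }
  b <- vis[rows, , drop = FALSE]
  ind <- x$individuals
  m <- match(b$id, ind$id)
  out <- data.frame(id = b$id,
                    sex = ind$sex[m],
                    age = ind$age_at_diagnosis[m] + b$duration,
                    bmi = b$bmi,
                    hba1c = b$hba1c,
                    c_peptide = b$c_peptide,
                    hdl = b$hdl,
                    baseline_duration = b$duration)
  # stable order: as in the individuals table
  out <- out[order(match(out$id, ind$id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
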