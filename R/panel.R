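#' Measurement-occasion schedules
#'
#' Preset nominal measurement schedules for the five-year cohort design:
#' quarterly follow-up during the first two years, annual thereafter.
#' `"stayer11"` (the default throughout the package) has 11 occasions at
#' months 0, 3, ..., 24, 36, 48; `"stayer12"` appends the month-60 wave.
#'
#' @param name preset name, `"stayer11"` or `"stayer12"`.
#' @return integer vector of months since baseline.
#' @export
#' @examples
#' schedule_preset("stayer11")
schedule_preset <- function(name = c("stayer11", "stayer12")) {
  name <- match.arg(name)
  s <- c(seq(0L, 24L, by = 3L), 36L, 48L)
  if (name == "stayer12") s <- c(s, 60L)
  s
}

#' Construct a longitudinal panel dataset
#'
#' The universal exchange object of the package: long-format records of the
#' three outcomes (drug-use consumption score DUDIT-C, life-satisfaction sum
#' score SWLS, psychological-distress index SCL-90-R GSI) plus the binary
#' time-varying covariate `drug_free_friends`, together with person-level
#' baseline covariates (age, gender) and the nominal occasion schedule.
#'
#' @param records data.frame with columns `person_id`, `month`, `dudit_c`,
#'   `swls`, `scl90r_gsi`, `drug_free_friends`. Missing cells are `NA`.
#' @param persons data.frame with columns `person_id`, `age`, `gender`
#'   (0/1, male = 1).
#' @param schedule nominal occasion months; defaults to the months present.
#' @param rescaled logical; `TRUE` when outcomes are on the downscaled
#'   analysis metric (DUDIT-C / 5, SWLS / 10). Instrument-range checks only
#'   apply to unrescaled data.
#' @param validate run integrity checks (default `TRUE`).
#' @return an object of class `rdsem_panel`.
#' @export
panel_dataset <- function(records, persons, schedule = NULL,
                          rescaled = FALSE, validate = TRUE) {
  records <- as.data.frame(records)
  persons <- as.data.frame(persons)
  missing_cols <- setdiff(.PANEL_COLS, names(records))
  if (length(missing_cols))
    stop("records lack required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!all(c("person_id", "age", "gender") %in% names(persons)))
    stop("persons needs columns person_id, age, gender", call. = FALSE)
  records$month <- as.integer(records$month)
  if (is.null(schedule)) schedule <- sort(unique(records$month))
  schedule <- sort(unique(as.integer(schedule)))
  records <- records[order(records$person_id, records$month),
                     .PANEL_COLS, drop = FALSE]
  rownames(records) <- NULL
  persons <- persons[order(persons$person_id),
                     c("person_id", "age", "gender"), drop = FALSE]
  rownames(persons) <- NULL
  x <- structure(list(records = records, persons = persons,
                      schedule = schedule, rescaled = isTRUE(rescaled),
                      lattice = NULL, step = NULL),
                 class = "rdsem_panel")
  if (validate) validate_panel(x)
  x
}

#' Validate panel invariants
#'
#' Checks uniqueness of (person, month) pairs, membership of record months in
#' the schedule (or lattice, after expansion), instrument ranges on unrescaled
#' data, completeness of the person table and the age inclusion criterion
#' (>= 16 years).
#'
#' @param x an `rdsem_panel`.
#' @return `x`, invisibly; errors describe the offending rows.
#' @export
validate_panel <- function(x) {
  stopifnot(inherits(x, "rdsem_panel"))
  r <- x$records
  key <- paste(r$person_id, r$month)
  if (anyDuplicated(key))
    stop("duplicate (person_id, month) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  months_ok <- if (is.null(x$lattice)) x$schedule else x$lattice
  bad <- which(!(r$month %in% months_ok))
  if (length(bad))
    stop("record month(s) outside the schedule at row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  if (!x$rescaled) {
    for (col in names(.OUTCOME_RANGES)) {
      rng <- .OUTCOME_RANGES[[col]]
      v <- r[[col]]
      bad <- which(!is.na(v) & (v < rng[1] | v > rng[2]))
      if (length(bad))
        stop(col, " out of range [", rng[1], ", ", rng[2], "] at row(s) ",
             paste(head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  dff <- r$drug_free_friends
  if (any(!is.na(dff) & !(dff %in% c(0, 1))))
    stop("drug_free_friends must be binary 0/1 or NA", call. = FALSE)
  orphan <- setdiff(unique(r$person_id), x$persons$person_id)
  if (length(orphan))
    stop("records reference unknown person(s): ",
         paste(head(orphan, 5), collapse = ", "), call. = FALSE)
  if (any(x$persons$age < 16))
    stop("age below the inclusion minimum of 16 for person(s): ",
         paste(x$persons$person_id[x$persons$age < 16], collapse = ", "),
         call. = FALSE)
  invisible(x)
}

#' @export
print.rdsem_panel <- function(x, ...) {
  cat("Longitudinal panel:", nrow(x$persons), "persons,",
      nrow(x$records), "records\n")
  cat("  schedule (months):", paste(x$schedule, collapse = " "), "\n")
  if (!is.null(x$lattice))
    cat("  lattice-expanded: step", x$step, "months,",
        length(x$lattice), "occasions\n")
  cat("  outcomes", if (x$rescaled) "rescaled (analysis metric)"
      else "on instrument metric", "\n")
  invisible(x)
}

#' Read a panel from long-format CSV
#'
#' Columns: `person_id, month, dudit_c, swls, scl90r_gsi, drug_free_friends,
#' age, gender`. Missing cells are empty (no sentinel codes). Person-level
#' columns must be constant within person.
#'
#' @param path CSV file path.
#' @param rescaled whether the stored outcomes are on the analysis metric.
#' @return an `rdsem_panel`.
#' @export
read_panel <- function(path, rescaled = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c(.PANEL_COLS, "age", "gender")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (pc in c("age", "gender")) {
    rng <- tapply(d[[pc]], d$person_id, function(v) length(unique(v[!is.na(v)])))
    if (any(rng > 1))
      stop(pc, " varies within person(s): ",
           paste(names(rng)[rng > 1], collapse = ", "), call. = FALSE)
  }
  persons <- d[!duplicated(d$person_id), c("person_id", "age", "gender")]
  panel_dataset(d[.PANEL_COLS], persons, rescaled = rescaled)
}

#' Write a panel to long-format CSV
#'
#' Inverse of [read_panel()]: stable column order, missing cells written as
#' empty strings.
#'
#' @param data an `rdsem_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(data, path) {
  stopifnot(inherits(data, "rdsem_panel"))
  out <- merge(data$records, data$persons, by = "person_id", sort = FALSE)
  out <- out[order(out$person_id, out$month),
             c(.PANEL_COLS, "age", "gender"), drop = FALSE]
  if (nrow(data$records) == 0)  # header-only file for an empty panel
    out <- out[0, c(.PANEL_COLS, "age", "gender"), drop = FALSE]
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Downscale outcomes to the analysis metric
#'
#' Divides DUDIT-C by `dudit_factor` and SWLS by `swls_factor` (the GSI is
#' already on a comparable 0-4 scale and is untouched) so the three outcomes
#' live on similar ranges, which eases MCMC convergence. `inverse = TRUE`
#' undoes the rescaling exactly.
#'
#' @param data an `rdsem_panel`.
#' @param dudit_factor,swls_factor positive divisors (defaults 5 and 10).
#' @param inverse undo a previous rescaling.
#' @return the rescaled `rdsem_panel` (flag `rescaled` toggled).
#' @export
rescale_outcomes <- function(data, dudit_factor = 5, swls_factor = 10,
                             inverse = FALSE) {
  stopifnot(inherits(data, "rdsem_panel"),
            dudit_factor > 0, swls_factor > 0)
  if (!inverse && data$rescaled)
    stop("outcomes are already rescaled", call. = FALSE)
  if (inverse && !data$rescaled)
    stop("outcomes are not rescaled; nothing to invert", call. = FALSE)
  f <- if (inverse) c(dudit_factor, swls_factor) else
    c(1 / dudit_factor, 1 / swls_factor)
  data$records$dudit_c <- data$records$dudit_c * f[1]
  data$records$swls <- data$records$swls * f[2]
  data$rescaled <- !inverse
  data
}

#' Expand the measurement schedule onto an equally spaced time lattice
#'
#' Inserts phantom occasions (records with all outcomes missing) at every
#' multiple of `step_months` between the schedule minimum and maximum, for
#' every person. After expansion the spacing is constant, so a lag-1 term in
#' the autoregression always means one `step_months` interval; phantom cells
#' are treated like any other missing outcome. Idempotent.
#'
#' @param data an `rdsem_panel`.
#' @param step_months lattice step (default 3, the quarterly interval).
#' @return the expanded `rdsem_panel` with fields `lattice` and `step` set.
#' @export
expand_time_lattice <- function(data, step_months = 3L) {
  stopifnot(inherits(data, "rdsem_panel"))
  step_months <- as.integer(step_months)
  if (step_months <= 0) stop("step_months must be positive", call. = FALSE)
  sched <- data$schedule
  if (length(sched) < 2) stop("schedule has fewer than 2 occasions", call. = FALSE)
  if (step_months > min(diff(sched)))
    stop("step_months (", step_months,
         ") exceeds the smallest schedule gap (", min(diff(sched)), ")",
         call. = FALSE)
  if (any(sched %% step_months != 0))
    stop("schedule months are not multiples of step_months", call. = FALSE)
  lattice <- seq(min(sched), max(sched), by = step_months)
  r <- data$records
  ids <- data$persons$person_id
  full <- expand.grid(month = lattice, person_id = ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key_have <- paste(r$person_id, r$month)
  key_full <- paste(full$person_id, full$month)
  add <- full[!(key_full %in% key_have), c("person_id", "month")]
  if (nrow(add)) {
    add$dudit_c <- add$swls <- add$scl90r_gsi <- NA_real_
    add$drug_free_friends <- NA_real_
    r <- rbind(r[.PANEL_COLS], add[.PANEL_COLS])
  }
  r <- r[order(r$person_id, r$month), , drop = FALSE]
  rownames(r) <- NULL
  data$records <- r
  data$lattice <- lattice
  data$step <- step_months
  validate_panel(data)
  data
}

is_lattice_expanded <- function(data) !is.null(data$lattice)

#' Dichotomize drug use
#'
#' Binary use indicator from the unrescaled DUDIT-C consumption score:
#' 0 at the abstinence cutoff, 1 above it, `NA` propagated.
#'
#' @param data an `rdsem_panel` on the instrument metric.
#' @param cutoff abstinence cutoff (default 0: scoring zero vs all others).
#' @return data.frame `person_id, month, use`.
#' @export
dichotomize_dudit <- function(data, cutoff = 0) {
  stopifnot(inherits(data, "rdsem_panel"))
  if (data$rescaled)
    stop("dichotomization needs unrescaled scores; apply rescale_outcomes(",
         "inverse = TRUE) first", call. = FALSE)
  d <- data$records
  data.frame(person_id = d$person_id, month = d$month,
             use = ifelse(is.na(d$dudit_c), NA_real_,
                          as.numeric(d$dudit_c > cutoff)))
}

#' Screen a binary time-varying covariate for usable variance
#'
#' A binary covariate that is constant within almost every person carries no
#' within-level information and destabilises the model; this reports the
#' proportion of persons whose observed values never change and the pooled
#' variance, and recommends dropping the covariate when the constancy
#' proportion reaches `threshold`.
#'
#' @param data an `rdsem_panel`.
#' @param covariate record column name (default `drug_free_friends`).
#' @param threshold constancy proportion at which to recommend dropping.
#' @return list with `decision` ("keep"/"drop"), `prop_constant`,
#'   `pooled_variance` and the per-person table.
#' @export
screen_low_variance_covariate <- function(data,
                                          covariate = "drug_free_friends",
                                          threshold = 0.9) {
  stopifnot(inherits(data, "rdsem_panel"))
  if (!covariate %in% names(data$records))
    stop("covariate '", covariate, "' not found in records", call. = FALSE)
  v <- data$records[[covariate]]
  ok <- !is.na(v)
  if (any(!(v[ok] %in% c(0, 1))))
    stop("covariate '", covariate, "' is not binary", call. = FALSE)
  per <- tapply(v[ok], data$records$person_id[ok],
                function(z) length(unique(z)) <= 1)
  prop_const <- if (length(per)) mean(per) else NA_real_
  pooled <- if (sum(ok) > 1) var(v[ok]) else 0
  decision <- if (!is.na(prop_const) && prop_const >= threshold) "drop" else "keep"
  structure(list(decision = decision, prop_constant = prop_const,
                 pooled_variance = pooled, threshold = threshold,
                 per_person = per),
            class = "rdsem_screen")
}

#' @export
print.rdsem_screen <- function(x, ...) {
  cat(sprintf(
    "Covariate screening: %s (%.1f%% of persons time-constant, pooled variance %.4f)\n",
    x$decision, 100 * x$prop_constant, x$pooled_variance))
  invisible(x)
}
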