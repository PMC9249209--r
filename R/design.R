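#' Trial design for a stepped-wedge study with long before/after phases
#'
#' Describes a seven-site stepped-wedge cluster randomised design with three
#' consecutive phases (validation, randomisation, implementation) over a
#' 24-month window. Every site starts under standard care (control) and
#' switches permanently to the intervention pathway on its crossover day;
#' sites are randomised to one of three planned crossover steps but the
#' actual switch dates may differ.
#'
#' Phases partition the study window half-open: validation is
#' `[study_start_day, validation_end_day)`, randomisation is
#' `[validation_end_day, randomisation_end_day)` and implementation runs to
#' `study_end_day` inclusive. The crossover day itself counts as
#' intervention (the pathway is live from the implementation date).
#'
#' The default design has four sites switching at the first actual crossover
#' point, one at the second and two at the third, with two sites deviating
#' from their planned (randomised) step.
#'
#' @param site_ids character vector of exactly 7 site labels.
#' @param planned_crossover_day integer vector, per-site randomised crossover
#'   day (days since study start); must take exactly 3 distinct values.
#' @param actual_crossover_day integer vector, per-site actual crossover day;
#'   each must lie inside the randomisation phase.
#' @param study_start_day,study_end_day integers delimiting the study window.
#' @param validation_end_day,randomisation_end_day integers delimiting the
#'   three phases (half-open boundaries).
#' @param calendar_origin `Date`, the calendar date of day 0. Used for
#'   season coding, monthly cluster periods and calendar-matched windows.
#' @return An object of class `sw_design`.
#' @export
sw_design <- function(site_ids = paste0("site", 1:7),
                      planned_crossover_day = c(319L, 319L, 364L, 364L, 364L, 410L, 364L),
                      actual_crossover_day = c(319L, 319L, 319L, 319L, 364L, 410L, 410L),
                      study_start_day = 0L,
                      study_end_day = 730L,
                      validation_end_day = 273L,
                      randomisation_end_day = 456L,
                      calendar_origin = as.Date("2016-06-01")) {
  site_ids <- as.character(site_ids)
  if (length(site_ids) != 7L || anyDuplicated(site_ids))
    stop("a design requires exactly 7 distinct site ids", call. = FALSE)
  planned_crossover_day <- as.integer(planned_crossover_day)
  actual_crossover_day <- as.integer(actual_crossover_day)
  if (length(planned_crossover_day) != 7L || length(actual_crossover_day) != 7L)
    stop("crossover days must be given per site (length 7)", call. = FALSE)
  if (length(unique(planned_crossover_day)) != 3L)
    stop("planned crossover days must take exactly 3 distinct values (the randomised steps)",
         call. = FALSE)
  if (!(study_start_day <= validation_end_day &&
        validation_end_day <= randomisation_end_day &&
        randomisation_end_day <= study_end_day))
    stop("phase boundaries must be ordered: start <= validation end <= randomisation end <= study end",
         call. = FALSE)
  if (any(actual_crossover_day < validation_end_day |
          actual_crossover_day > randomisation_end_day))
    stop("every actual crossover day must lie within the randomisation phase",
         call. = FALSE)
  days <- c(planned_crossover_day, actual_crossover_day)
  if (any(days < study_start_day | days > study_end_day))
    stop("crossover days must lie inside the study window", call. = FALSE)
  calendar_origin <- as.Date(calendar_origin)

  structure(list(site_ids = site_ids,
                 planned_crossover_day = planned_crossover_day,
                 actual_crossover_day = actual_crossover_day,
                 study_start_day = as.integer(study_start_day),
                 study_end_day = as.integer(study_end_day),
                 validation_end_day = as.integer(validation_end_day),
                 randomisation_end_day = as.integer(randomisation_end_day),
                 calendar_origin = calendar_origin),
            class = "sw_design")
}

#' @export
print.sw_design <- function(x, ...) {
  cat("Stepped-wedge trial design: 7 sites,", x$study_end_day - x$study_start_day,
      "days\n")
  cat(sprintf("  phases (half-open): validation [%d,%d), randomisation [%d,%d), implementation [%d,%d]\n",
              x$study_start_day, x$validation_end_day, x$validation_end_day,
              x$randomisation_end_day, x$randomisation_end_day, x$study_end_day))
  cat("  calendar origin (day 0):", format(x$calendar_origin), "\n")
  print(data.frame(site = x$site_ids, planned = x$planned_crossover_day,
                   actual = x$actual_crossover_day))
  invisible(x)
}

crossover_days <- function(design, timing = c("actual", "planned")) {
  timing <- match.arg(timing)
  d <- if (timing == "actual") design$actual_crossover_day else design$planned_crossover_day
  stats::setNames(d, design$site_ids)
}

#' Condition assignment at a given presentation day
#'
#' A record is under the intervention condition if and only if its
#' presentation day is on or after the site's crossover day (the crossover
#' day itself counts as intervention).
#'
#' @param day integer vector of presentation days since study start.
#' @param crossover_day integer vector (recycled) of site crossover days.
#' @param design optional `sw_design`; when supplied, `day` is checked
#'   against the study window.
#' @return character vector, `"control"` or `"intervention"`.
#' @export
assign_condition <- function(day, crossover_day, design = NULL) {
  if (!is.null(design) &&
      any(day < design$study_start_day | day > design$study_end_day))
    stop("presentation day outside the study window [",
         design$study_start_day, ", ", design$study_end_day, "]", call. = FALSE)
  ifelse(day >= crossover_day, "intervention", "control")
}

#' Season of a calendar month
#'
#' Meteorological seasons: Winter (Dec-Feb, the reference level for dummy
#' coding), Spring (Mar-May), Summer (Jun-Aug), Autumn (Sep-Nov).
#'
#' @param calendar_month integer vector in 1..12.
#' @return factor with levels Winter, Spring, Summer, Autumn (Winter first).
#' @export
season_of <- function(calendar_month) {
  if (any(is.na(calendar_month)) || any(calendar_month < 1 | calendar_month > 12))
    stop("calendar_month must be in 1..12", call. = FALSE)
  map <- c("Winter", "Winter", "Spring", "Spring", "Spring", "Summer",
           "Summer", "Summer", "Autumn", "Autumn", "Autumn", "Winter")
  factor(map[calendar_month], levels = c("Winter", "Spring", "Summer", "Autumn"))
}

#' Presentation time centred on the enrolment midpoint
#'
#' @param day numeric vector of presentation days.
#' @param enrolment_mid midpoint of the minimum and maximum presentation day
#'   in the analysis population; defaults to the midpoint of `day` itself.
#' @return numeric vector `day - enrolment_mid`.
#' @export
centred_time <- function(day, enrolment_mid = (min(day) + max(day)) / 2) {
  day - enrolment_mid
}

#' Exposure time: days since a site implemented the intervention
#'
#' Zero for records under the control condition, `day - crossover_day`
#' otherwise.
#'
#' @inheritParams assign_condition
#' @return numeric vector, non-negative.
#' @export
exposure_time <- function(day, crossover_day) {
  pmax(day - crossover_day, 0)
}

phase_levels <- c("validation", "randomisation", "implementation")

#' Phase membership of a presentation day
#'
#' @param day integer vector.
#' @param design an `sw_design`.
#' @return factor with levels validation, randomisation, implementation.
#' @export
phase_of <- function(day, design) {
  if (any(day < design$study_start_day | day > design$study_end_day))
    stop("presentation day outside the study window", call. = FALSE)
  ph <- ifelse(day < design$validation_end_day, "validation",
               ifelse(day < design$randomisation_end_day, "randomisation",
                      "implementation"))
  factor(ph, levels = phase_levels)
}

day_to_date <- function(day, design) design$calendar_origin + day

#' Derive analysis variables from raw trial records
#'
#' Adds the deterministic derivations shared by the generator and the
#' analysis suite: calendar date and month, season, phase, the site's
#' crossover day under the requested timing, condition, and exposure time.
#'
#' @param data data frame with at least `site` and `day` columns.
#' @param design an `sw_design`.
#' @param timing use the `"actual"` crossover dates (default) or the
#'   `"planned"` randomised dates (the as-randomised analysis).
#' @return `data` with columns `date`, `cmonth`, `season`, `phase`,
#'   `crossover_day`, `condition` (factor, control reference) and
#'   `exposure` appended.
#' @export
derive_variables <- function(data, design, timing = c("actual", "planned")) {
  timing <- match.arg(timing)
  if (!all(data$site %in% design$site_ids))
    stop("dataset contains sites absent from the design", call. = FALSE)
  cross <- crossover_days(design, timing)[as.character(data$site)]
  data$date <- day_to_date(data$day, design)
  lt <- as.POSIXlt(data$date)
  data$cmonth <- lt$mon + 1L
  data$season <- season_of(data$cmonth)
  data$phase <- phase_of(data$day, design)
  data$crossover_day <- unname(cross)
  data$condition <- factor(assign_condition(data$day, cross, design),
                           levels = c("control", "intervention"))
  data$exposure <- exposure_time(data$day, cross)
  data
}

in_calendar_window <- function(date, inclusive = TRUE) {
  lt <- as.POSIXlt(date)
  m <- lt$mon + 1L
  d <- lt$mday
  if (inclusive) {
    (m > 3 & m < 9) | (m == 3 & d >= 3) | (m == 9 & d <= 3)
  } else {
    (m > 3 & m < 9) | (m == 3 & d > 3) | (m == 9 & d < 3)
  }
}

#' Calendar-matched before/after population
#'
#' Restricts a dataset to validation- and implementation-phase records whose
#' calendar date falls between 3 March and 3 September (inclusive by
#' default) of any study year. Randomisation-phase records are excluded, so
#' the filtered data support a seasonally balanced before/after comparison.
#'
#' @inheritParams derive_variables
#' @param inclusive logical; are the window boundary dates (3 March and
#'   3 September) included? Default `TRUE`.
#' @return the filtered data frame.
#' @export
filter_calendar_matched <- function(data, design, inclusive = TRUE) {
  ph <- phase_of(data$day, design)
  keep <- ph %in% c("validation", "implementation") &
    in_calendar_window(day_to_date(data$day, design), inclusive)
  out <- data[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    message("calendar-matched filter returned an empty dataset")
  out
}

#' Randomisation-phase population
#'
#' Retains records with `validation_end_day <= day < randomisation_end_day`.
#'
#' @inheritParams derive_variables
#' @return the filtered data frame.
#' @export
filter_randomisation_phase <- function(data, design) {
  keep <- data$day >= design$validation_end_day &
    data$day < design$randomisation_end_day
  data[keep, , drop = FALSE]
}

month_index <- function(day, design) {
  lt0 <- as.POSIXlt(design$calendar_origin)
  lt <- as.POSIXlt(day_to_date(day, design))
  (lt$year - lt0$year) * 12L + (lt$mon - lt0$mon)
}

#' Cluster-period table: events and denominators by site and calendar month
#'
#' Cluster periods are site-by-calendar-month cells. The table covers the
#' full grid of design sites by study months, so cells with no
#' presentations appear with zero counts; totals are conserved exactly.
#'
#' @inheritParams derive_variables
#' @return data frame with columns `site`, `month` (calendar month index
#'   since the study's first month), `events`, `denominator`, of class
#'   `sw_cluster_periods`.
#' @export
tabulate_cluster_periods <- function(data, design) {
  months <- seq(0L, month_index(design$study_end_day, design))
  grid <- expand.grid(site = design$site_ids, month = months,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$site, grid$month), , drop = FALSE]
  rownames(grid) <- NULL
  key <- function(site, month) paste(site, month, sep = "\r")
  grid$events <- 0L
  grid$denominator <- 0L
  if (nrow(data) > 0L) {
    m <- month_index(data$day, design)
    k <- key(data$site, m)
    den <- table(k)
    ev <- tapply(data$safety_event, k, sum)
    gk <- key(grid$site, grid$month)
    idx <- match(names(den), gk)
    if (anyNA(idx)) stop("presentation outside the design's month grid", call. = FALSE)
    grid$denominator[idx] <- as.integer(den)
    grid$events[match(names(ev), gk)] <- as.integer(ev)
  }
  class(grid) <- c("sw_cluster_periods", "data.frame")
  grid
}

# ---- dataset / design serialisation ----------------------------------------

hx_cols <- c("hx_ihd", "hx_mi", "hx_cvd", "hx_diabetes", "hx_pci", "hx_cabg",
             "hx_aspirin", "hx_lipid", "hx_betablocker", "hx_acei")

dataset_cols <- c("site", "day", "age", "sex", "simd", hx_cols,
                  "los_hours", "safety_event", "synthetic")

#' Read / write patient-level trial data
#'
#' The on-disk format is plain CSV with one row per presentation and the
#' fixed column schema: `site`, `day`, `age`, `sex` (1 = female), `simd`
#' (deprivation quintile 1-5), ten binary history flags (`hx_ihd`, `hx_mi`,
#' `hx_cvd`, `hx_diabetes`, `hx_pci`, `hx_cabg`, `hx_aspirin`, `hx_lipid`,
#' `hx_betablocker`, `hx_acei`), `los_hours`, `safety_event` and
#' `synthetic` (1 marks augmentation prior records). Lines starting with
#' `#` are metadata comments and are skipped on read.
#'
#' @param path file path.
#' @return `read_trial_data` returns the data frame.
#' @export
read_trial_data <- function(path) {
  out <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(dataset_cols, names(out))
  if (length(miss))
    stop("trial data file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out
}

#' @rdname read_trial_data
#' @param data data frame in the standard schema.
#' @param meta optional named character vector written as `# key: value`
#'   header comments (e.g. seed, config hash).
#' @export
write_trial_data <- function(data, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(paste0("# ", names(meta), ": ", unname(meta)), con)
  utils::write.csv(data[, intersect(dataset_cols, names(data)), drop = FALSE],
                   con, row.names = FALSE)
  invisible(path)
}

#' Read / write a trial design as YAML
#'
#' @param path file path to a YAML file with the `sw_design` fields.
#' @return `read_design` returns an `sw_design`.
#' @export
read_design <- function(path) {
  y <- yaml::read_yaml(path)
  sw_design(site_ids = y$site_ids,
            planned_crossover_day = y$planned_crossover_day,
            actual_crossover_day = y$actual_crossover_day,
            study_start_day = y$study_start_day %||% 0L,
            study_end_day = y$study_end_day %||% 730L,
            validation_end_day = y$validation_end_day,
            randomisation_end_day = y$randomisation_end_day,
            calendar_origin = y$calendar_origin %||% "2016-06-01")
}

#' @rdname read_design
#' @param design an `sw_design`.
#' @export
write_design <- function(design, path) {
  y <- unclass(design)
  y$calendar_origin <- format(y$calendar_origin)
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
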