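# Academic-year arithmetic: PGY level as of a date, enrollment windows,
# report-schedule applicability, and the graduate/active roster partition.

#' Academic calendar
#'
#' Training programs run on an academic year; the default July 1 – June 30
#' cycle is the norm for US residency programs. `year_start` is given as
#' `c(month, day)`; the year ends the day before the next cycle starts.
#'
#' @param year_start Integer vector `c(month, day)`, default July 1.
#' @return An `academic_calendar` object.
#' @export
academic_calendar <- function(year_start = c(7L, 1L)) {
  stopifnot(length(year_start) == 2, year_start[1] %in% 1:12,
            year_start[2] %in% 1:31)
  structure(list(start_month = as.integer(year_start[1]),
                 start_day = as.integer(year_start[2])),
            class = "academic_calendar")
}

# calendar year in which the academic year containing `date` ends
# (July 1 2019 .. June 30 2020 -> 2020 under the default calendar)
ay_end_year <- function(date, calendar = academic_calendar()) {
  d <- as.Date(date)
  m <- as.integer(format(d, "%m"))
  dd <- as.integer(format(d, "%d"))
  y <- as.integer(format(d, "%Y"))
  started <- (m > calendar$start_month) |
    (m == calendar$start_month & dd >= calendar$start_day)
  ifelse(started, y + 1L, y)
}

#' Postgraduate-year level of a class on a date
#'
#' A class is labelled by its graduation year; its members are PGY1 in the
#' academic year ending `program_length - 1` years before graduation. The
#' level on a date is `program_length - (class_year - AY_end_year(date))`.
#' Values past the program length mean the class has graduated; values
#' below 1 mean it has not yet enrolled.
#'
#' @param class_year Integer vector of graduation years.
#' @param as_of A date.
#' @param calendar An [academic_calendar()].
#' @param program_length Program length in years (default 3).
#' @return Character vector: `"PGY1"`..`"PGY<n>"`, `"GRADUATED"` or
#'   `"PRE_ENROLLMENT"`.
#' @examples
#' pgy_level(2022, as.Date("2019-09-15"))  # "PGY1"
#' @export
pgy_level <- function(class_year, as_of, calendar = academic_calendar(),
                      program_length = 3L) {
  lvl <- program_length - (as.integer(class_year) - ay_end_year(as_of, calendar))
  dplyr::case_when(
    lvl > program_length ~ "GRADUATED",
    lvl < 1 ~ "PRE_ENROLLMENT",
    .default = paste0("PGY", lvl)
  )
}

#' Enrollment window of a class
#'
#' @inheritParams pgy_level
#' @return A tibble with `class_year`, `window_start`, `window_end`
#'   (Dates); the window spans the class's full residency, e.g. the class
#'   of 2017 in a 3-year program trains 2014-07-01 through 2017-06-30.
#' @export
enrollment_window <- function(class_year, calendar = academic_calendar(),
                              program_length = 3L) {
  cy <- as.integer(class_year)
  start <- as.Date(sprintf("%d-%02d-%02d", cy - program_length,
                           calendar$start_month, calendar$start_day))
  # day before the cycle restarts, program_length years later
  end <- as.Date(sprintf("%d-%02d-%02d", cy, calendar$start_month,
                         calendar$start_day)) - 1L
  tibble(class_year = cy, window_start = start, window_end = end)
}

#' Report dates applicable to a class
#'
#' A semiannual report reaches a class if its date falls inside the
#' class's enrollment window (inclusive on both ends): a report during the
#' class's first month still counts, and none are delivered after
#' graduation.
#'
#' @param class_year A single graduation year.
#' @param report_dates Vector of report dates (Date or ISO strings).
#' @inheritParams pgy_level
#' @return A list with `n` (count) and `dates` (the applicable dates,
#'   sorted).
#' @examples
#' applicable_reports(2022, c("2019-04-01", "2019-09-01", "2020-04-01"))$n  # 2
#' @export
applicable_reports <- function(class_year, report_dates,
                               calendar = academic_calendar(),
                               program_length = 3L) {
  stopifnot(length(class_year) == 1)
  rd <- sort(as.Date(report_dates))
  win <- enrollment_window(class_year, calendar, program_length)
  keep <- rd >= win$window_start & rd <= win$window_end
  list(n = sum(keep), dates = rd[keep])
}

#' Cohort configuration for one report run
#'
#' @param as_of Date the report is drawn (encounters after it are ignored).
#' @param benchmark_classes Class years forming the graduate benchmark;
#'   all must have graduated by `as_of`.
#' @param report_dates Scheduled report dates (for schedule summaries).
#' @param program_length Program length in years.
#' @param calendar An [academic_calendar()].
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(as_of, benchmark_classes,
                          report_dates = as.Date(character()),
                          program_length = 3L,
                          calendar = academic_calendar()) {
  as_of <- as.Date(as_of)
  benchmark_classes <- as.integer(benchmark_classes)
  lvl <- pgy_level(benchmark_classes, as_of, calendar, program_length)
  if (any(lvl != "GRADUATED")) {
    abort(sprintf("Benchmark class(es) not graduated by %s: %s", as_of,
                  paste(benchmark_classes[lvl != "GRADUATED"], collapse = ", ")),
          class = "caselogr_bad_config")
  }
  structure(
    list(as_of = as_of, benchmark_classes = benchmark_classes,
         report_dates = sort(as.Date(report_dates)),
         program_length = as.integer(program_length), calendar = calendar),
    class = "cohort_config"
  )
}

#' Partition a roster into graduate benchmark and active classes
#'
#' @param roster Roster tibble ([read_roster()]).
#' @param config A [cohort_config()].
#' @return A `cohort_partition`: list with `graduates` (roster subset),
#'   `active` (roster subset with a `pgy` column), and `counts` (tibble of
#'   class sizes by role).
#' @examples
#' roster <- tibble::tibble(resident_id = c("a", "b"), class_year = c(2019L, 2021L))
#' cfg <- cohort_config("2020-04-01", benchmark_classes = 2016:2019)
#' partition_roster(roster, cfg)$counts
#' @export
partition_roster <- function(roster, config) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(config$benchmark_classes) == 0) {
    abort("Benchmark class set is empty", class = "caselogr_empty_benchmark")
  }
  grads <- roster |> filter(.data$class_year %in% config$benchmark_classes)
  if (nrow(grads) == 0) {
    abort("No roster member belongs to a benchmark class",
          class = "caselogr_empty_benchmark")
  }
  active <- roster |>
    filter(!.data$class_year %in% config$benchmark_classes) |>
    mutate(pgy = pgy_level(.data$class_year, config$as_of, config$calendar,
                           config$program_length))
  counts <- bind_rows(
    grads |> count(.data$class_year, name = "n") |> mutate(role = "graduate"),
    active |> count(.data$class_year, name = "n") |> mutate(role = "active")
  )
  structure(list(graduates = grads, active = active, counts = counts),
            class = "cohort_partition")
}

#' @export
print.cohort_partition <- function(x, ...) {
  cat(sprintf("<cohort_partition: %d graduates, %d active (%d classes)>\n",
              nrow(x$graduates), nrow(x$active),
              dplyr::n_distinct(x$active$class_year)))
  invisible(x)
}
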