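# Volume, variety, cohort benchmarks and percent-of-benchmark
# normalization.
#
# Volume is the number of UNIQUE qualifying visits: an encounter carrying
# two codes from the same group counts once for that group; an encounter
# with codes in two groups counts once in each. Class averages include
# members with zero qualifying encounters — leaving them out would inflate
# peer benchmarks and hide exactly the gaps the reports exist to expose.

#' Count unique qualifying visits per resident and group
#'
#' For every roster resident, counts the distinct encounters they authored
#' within their own enrollment window (clipped at the run's as-of date)
#' that carry at least one diagnosis assigned to each group. Codes mapping
#' to no group are tallied, not errors: curated sets exclude common
#' self-limited diagnoses by design.
#'
#' @param dataset A `caselog_dataset` from [link_dataset()].
#' @param group_set A `group_set`.
#' @param config A [cohort_config()]; supplies the as-of date, program
#'   length and calendar that define each resident's counting window.
#' @return A `volume_matrix`: tibble with columns `resident_id`, `group`,
#'   `count`, one row per roster resident x group (zero cells present).
#'   Attributes: `group_order`, `n_unmapped` (in-window diagnosis
#'   instances assigned to no group), `as_of`.
#' @export
count_volumes <- function(dataset, group_set, config) {
  stopifnot(inherits(dataset, "caselog_dataset"),
            inherits(group_set, "group_set"),
            inherits(config, "cohort_config"))
  enc <- dataset$encounters
  roster <- dataset$roster
  gnames <- group_names(group_set)

  windows <- enrollment_window(unique(roster$class_year),
                               config$calendar, config$program_length) |>
    mutate(window_end = pmin(.data$window_end, config$as_of))

  long <- enc |>
    select("encounter_id", "resident_id", "service_date", "diagnoses") |>
    tidyr::unnest_longer("diagnoses", values_to = "code") |>
    left_join(roster, by = "resident_id") |>
    left_join(windows, by = "class_year") |>
    filter(.data$service_date >= .data$window_start,
           .data$service_date <= .data$window_end)

  hits <- match_group_table(unique(long$code), group_set)
  n_unmapped <- sum(!long$code %in% hits$code)

  counted <- long |>
    inner_join(hits, by = "code", relationship = "many-to-many") |>
    distinct(.data$resident_id, .data$group, .data$encounter_id) |>
    count(.data$resident_id, .data$group, name = "count")

  out <- tidyr::crossing(resident_id = roster$resident_id, group = gnames) |>
    left_join(counted, by = c("resident_id", "group")) |>
    mutate(count = tidyr::replace_na(.data$count, 0L),
           group = factor(.data$group, levels = gnames)) |>
    arrange(.data$resident_id, .data$group) |>
    mutate(group = as.character(.data$group))

  structure(out, class = c("volume_matrix", class(out)),
            group_order = gnames, n_unmapped = n_unmapped,
            as_of = config$as_of)
}

#' Variety: number of distinct groups a resident has encountered
#'
#' @param matrix A `volume_matrix`.
#' @param resident_id A single resident identifier.
#' @return Integer count of groups with at least one qualifying visit.
#' @export
variety <- function(matrix, resident_id) {
  stopifnot(inherits(matrix, "volume_matrix"), length(resident_id) == 1)
  rows <- matrix[matrix$resident_id == resident_id, ]
  if (nrow(rows) == 0) {
    abort(sprintf("Unknown resident: %s", resident_id),
          class = "caselogr_unknown_resident")
  }
  sum(rows$count >= 1L)
}

#' Per-group mean volume over a cohort
#'
#' Arithmetic mean over every member of the subset, zero-count members
#' included; full precision is retained (rounding is a display concern).
#'
#' @param matrix A `volume_matrix`.
#' @param resident_ids Nonempty character vector of cohort members.
#' @return Tibble with `group` and `mean` (double), in group order.
#' @export
cohort_mean <- function(matrix, resident_ids) {
  stopifnot(inherits(matrix, "volume_matrix"))
  resident_ids <- unique(resident_ids)
  if (length(resident_ids) == 0) {
    abort("Cohort is empty", class = "caselogr_empty_cohort")
  }
  missing <- setdiff(resident_ids, unique(matrix$resident_id))
  if (length(missing) > 0) {
    abort(sprintf("Resident(s) absent from volume matrix: %s",
                  paste(missing, collapse = ", ")),
          class = "caselogr_unknown_resident")
  }
  gnames <- attr(matrix, "group_order")
  matrix |>
    filter(.data$resident_id %in% resident_ids) |>
    summarise(mean = sum(.data$count) / length(resident_ids), .by = "group") |>
    arrange(factor(.data$group, levels = gnames))
}

#' Percent of the graduate benchmark
#'
#' `100 * count / benchmark`, full precision. A zero benchmark yields a
#' flagged-undefined `NA`, never infinity; downstream renderers draw such
#' cells as gaps.
#'
#' @param count Non-negative numeric vector of visit counts.
#' @param benchmark Benchmark mean(s), recycled against `count`.
#' @return Numeric vector of percentages (may exceed 100), `NA` where the
#'   benchmark is zero.
#' @examples
#' percent_of_benchmark(c(463, 863, 5), c(863, 863, 0))
#' @export
percent_of_benchmark <- function(count, benchmark) {
  stopifnot(all(count >= 0, na.rm = TRUE))
  ifelse(benchmark > 0, 100 * count / benchmark, NA_real_)
}

# round half-up to match display tables (base round() is half-to-even)
round_half_up <- function(x, digits = 0) {
  out <- floor(abs(x) * 10^digits + 0.5) / 10^digits * sign(x)
  ifelse(is.na(x), NA_real_, out)
}

#' Build the benchmark table for a report run
#'
#' Computes the graduate benchmark (per-group mean over every benchmark
#' graduate's complete training window) and one class average per active
#' class as of the report date.
#'
#' @param matrix A `volume_matrix` (already windowed by [count_volumes()]).
#' @param partition A `cohort_partition` from [partition_roster()].
#' @return A `benchmark_table`: list with `graduate` (tibble `group`,
#'   `mean`), `classes` (tibble `class_year`, `pgy`, `group`, `mean`) and
#'   the partition. Means are full precision; use [tidy()] for a long view
#'   with display-rounded integers.
#' @export
build_benchmarks <- function(matrix, partition) {
  stopifnot(inherits(matrix, "volume_matrix"),
            inherits(partition, "cohort_partition"))
  if (nrow(partition$graduates) == 0) {
    abort("Graduate benchmark set is empty", class = "caselogr_empty_benchmark")
  }
  graduate <- cohort_mean(matrix, partition$graduates$resident_id)
  classes <- partition$active |>
    distinct(.data$class_year, .data$pgy) |>
    arrange(.data$class_year)
  if (nrow(classes) == 0) {
    class_means <- tibble(class_year = integer(), pgy = character(),
                          group = character(), mean = double())
    return(structure(list(graduate = graduate, classes = class_means,
                          partition = partition, as_of = attr(matrix, "as_of")),
                     class = "benchmark_table"))
  }
  class_means <- pmap(classes, function(class_year, pgy) {
    ids <- partition$active$resident_id[partition$active$class_year == class_year]
    cohort_mean(matrix, ids) |>
      mutate(class_year = class_year, pgy = pgy)
  }) |>
    list_rbind() |>
    select("class_year", "pgy", "group", "mean")
  structure(list(graduate = graduate, classes = class_means,
                 partition = partition, as_of = attr(matrix, "as_of")),
            class = "benchmark_table")
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat(sprintf("<benchmark_table: %d groups, %d graduates, %d active classes>\n",
              nrow(x$graduate), nrow(x$partition$graduates),
              dplyr::n_distinct(x$classes$class_year)))
  invisible(x)
}

#' Tidy a benchmark table
#'
#' One row per (cohort, group): `cohort` is `"graduate"` or the class
#' year; `mean` is full precision and `display` is the half-up-rounded
#' integer shown in reports.
#'
#' @param x A `benchmark_table`.
#' @param ... Unused.
#' @method tidy benchmark_table
#' @export
tidy.benchmark_table <- function(x, ...) {
  bind_rows(
    x$graduate |> mutate(cohort = "graduate", pgy = "GRADUATED"),
    x$classes |> mutate(cohort = as.character(.data$class_year)) |>
      select("cohort", "pgy", "group", "mean")
  ) |>
    mutate(display = round_half_up(.data$mean)) |>
    select("cohort", "pgy", "group", "mean", "display")
}

#' @describeIn tidy.benchmark_table One-row summary: cohort sizes and the
#'   as-of date.
#' @param ... Unused.
#' @method glance benchmark_table
#' @export
glance.benchmark_table <- function(x, ...) {
  tibble(
    n_groups = nrow(x$graduate),
    n_graduates = nrow(x$partition$graduates),
    n_active = nrow(x$partition$active),
    n_active_classes = dplyr::n_distinct(x$classes$class_year),
    as_of = x$as_of
  )
}
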