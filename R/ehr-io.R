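# Flat-file ingestion: encounter exports and resident rosters.
#
# Encounter CSV layout (header mandatory, UTF-8):
#   encounter_id,resident_id,patient_id,service_date,diagnoses
# with ISO-8601 dates and ";"-separated raw ICD-10 codes. Roster CSV:
#   resident_id,class_year

ENCOUNTER_COLS <- c("encounter_id", "resident_id", "patient_id",
                    "service_date", "diagnoses")

#' Read a resident-authored encounter export
#'
#' Each row is one visit note authored by a resident, carrying every ICD-10
#' visit diagnosis attached to the encounter. Codes are normalized via
#' [normalize_code()]; duplicate codes within one encounter collapse; rows
#' sharing an `encounter_id` are merged by unioning their diagnoses (some
#' source systems emit one row per diagnosis rather than per visit).
#'
#' @param path Path to the encounter CSV.
#' @param strict If `TRUE` (default) a malformed code raises an error; if
#'   `FALSE` malformed codes are dropped with a warning tally.
#' @return A tibble with columns `encounter_id`, `resident_id`,
#'   `patient_id`, `service_date` (Date) and `diagnoses` (list of
#'   normalized code vectors), one row per unique encounter.
#' @export
read_encounters <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    abort(sprintf("Encounter file not found: %s", path), class = "caselogr_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(ENCOUNTER_COLS, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Encounter file lacks column(s): %s", paste(missing, collapse = ", ")),
          class = "caselogr_parse_error")
  }
  raw <- raw[ENCOUNTER_COLS]
  rownum <- seq_len(nrow(raw)) + 1L  # header is line 1

  dates <- as.Date(raw$service_date, format = "%Y-%m-%d")
  bad_date <- is.na(dates)
  if (any(bad_date)) {
    abort(sprintf("Unparseable ISO-8601 service_date at row(s) %s",
                  paste(head(rownum[bad_date], 5), collapse = ", ")),
          class = "caselogr_parse_error")
  }
  blank <- is.na(raw$diagnoses) | !nzchar(str_trim(raw$diagnoses))
  if (any(blank)) {
    abort(sprintf("Empty diagnosis cell at row(s) %s",
                  paste(head(rownum[blank], 5), collapse = ", ")),
          class = "caselogr_parse_error")
  }

  diag <- map(strsplit(raw$diagnoses, ";", fixed = TRUE), function(x) {
    x <- str_trim(x)
    x <- x[nzchar(x)]
    codes <- normalize_code(x, strict = strict)
    unique(codes[!is.na(codes)])
  })

  tibble(
    encounter_id = raw$encounter_id,
    resident_id = raw$resident_id,
    patient_id = raw$patient_id,
    service_date = dates,
    diagnoses = diag
  ) |>
    summarise(
      resident_id = .data$resident_id[1],
      patient_id = .data$patient_id[1],
      service_date = .data$service_date[1],
      diagnoses = list(sort(unique(unlist(.data$diagnoses)))),
      .by = "encounter_id"
    )
}

#' Write encounters back to the flat-file layout
#'
#' Inverse of [read_encounters()] up to normalization and row order: one
#' row per encounter, diagnoses joined with `";"`.
#'
#' @param encounters Encounter tibble from [read_encounters()] or
#'   [simulate_encounters()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_encounters <- function(encounters, path) {
  out <- encounters |>
    mutate(diagnoses = map_chr(.data$diagnoses, paste, collapse = ";"),
           service_date = format(.data$service_date, "%Y-%m-%d"))
  readr::write_csv(out[ENCOUNTER_COLS], path, progress = FALSE)
  invisible(path)
}

#' Read a resident roster
#'
#' @param path Path to a CSV with columns `resident_id` and `class_year`
#'   (4-digit graduation year).
#' @return A tibble with `resident_id` (character) and `class_year`
#'   (integer).
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Roster file not found: %s", path), class = "caselogr_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("resident_id", "class_year") %in% names(raw))) {
    abort("Roster needs columns resident_id, class_year",
          class = "caselogr_parse_error")
  }
  yr <- suppressWarnings(as.integer(raw$class_year))
  bad <- is.na(yr) | yr < 1990 | yr > 2100
  if (any(bad)) {
    abort(sprintf("Implausible class_year value(s): %s",
                  paste(unique(raw$class_year[bad]), collapse = ", ")),
          class = "caselogr_parse_error")
  }
  if (anyDuplicated(raw$resident_id)) {
    abort(sprintf("Duplicate resident_id(s): %s",
                  paste(unique(raw$resident_id[duplicated(raw$resident_id)]),
                        collapse = ", ")),
          class = "caselogr_duplicate_resident")
  }
  tibble(resident_id = raw$resident_id, class_year = yr)
}

#' Link encounters to a roster
#'
#' Attributes every encounter to its authoring resident and checks that
#' the author is on the roster. In strict mode an off-roster author is an
#' error; in lenient mode those encounters are dropped and counted.
#'
#' @param encounters Encounter tibble ([read_encounters()]).
#' @param roster Roster tibble ([read_roster()]).
#' @param mode `"strict"` or `"lenient"`.
#' @return A `caselog_dataset`: list with `encounters`, `roster` and
#'   `n_orphaned` (encounters dropped in lenient mode).
#' @export
link_dataset <- function(encounters, roster, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (anyDuplicated(encounters$encounter_id)) {
    abort("encounter_id must be unique after merging", class = "caselogr_parse_error")
  }
  orphan <- !encounters$resident_id %in% roster$resident_id
  if (any(orphan) && mode == "strict") {
    abort(sprintf("Encounter(s) authored by off-roster resident(s): %s",
                  paste(unique(encounters$resident_id[orphan]), collapse = ", ")),
          class = "caselogr_orphaned_resident")
  }
  structure(
    list(encounters = encounters[!orphan, ], roster = roster,
         n_orphaned = sum(orphan)),
    class = "caselog_dataset"
  )
}

#' @export
print.caselog_dataset <- function(x, ...) {
  cat(sprintf("<caselog_dataset: %d encounters, %d residents on roster, %d orphaned>\n",
              nrow(x$encounters), nrow(x$roster), x$n_orphaned))
  invisible(x)
}
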