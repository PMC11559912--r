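# Compiled group sets: named bundles of code patterns plus the machinery to
# assign normalized codes to groups.

the <- new.env(parent = emptyenv())

new_group_set <- function(groups, version) {
  nms <- map_chr(groups, "name")
  if (anyDuplicated(nms)) {
    abort(sprintf("Duplicate group name(s): %s",
                  paste(unique(nms[duplicated(nms)]), collapse = ", ")),
          class = "caselogr_bad_group_set")
  }
  if (any(!nzchar(nms))) {
    abort("Group names must be nonempty", class = "caselogr_bad_group_set")
  }
  if (any(map_int(groups, ~ length(.x$patterns)) == 0)) {
    abort("Every group needs at least one code pattern",
          class = "caselogr_bad_group_set")
  }
  structure(list(groups = groups, version = version), class = "group_set")
}

#' Read diagnostic-group definitions from a config file
#'
#' The config (YAML or JSON) holds a `version` label and a `groups` list;
#' each group has a `name`, a `codes` list of raw tokens (see
#' [parse_pattern()] for the token grammar) and optional free-text `notes`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` group-definition file.
#' @return A `group_set`: an ordered list of compiled groups plus the
#'   config's version label.
#' @seealso [default_group_set()] for the shipped pediatric set.
#' @export
read_group_set <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Group config not found: %s", path), class = "caselogr_io_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$groups)) {
    abort("Group config must contain a `groups` list",
          class = "caselogr_bad_group_set")
  }
  groups <- map(raw$groups, function(g) {
    tokens <- as.character(unlist(g$codes))
    list(
      name = g$name,
      patterns = map(tokens, parse_pattern),
      notes = if (is.null(g$notes)) NA_character_ else as.character(g$notes)
    )
  })
  new_group_set(groups, version = raw$version %||% "unversioned")
}

#' The shipped pediatric continuity-clinic group set
#'
#' Twenty-two curated diagnostic groups spanning the bread and butter of
#' outpatient pediatrics (well checks, asthma, constipation, developmental
#' delay, ...) chosen to measure trainee exposure; common self-limited
#' conditions such as uncomplicated upper respiratory infections are
#' deliberately absent so that reports surface actionable gaps.
#'
#' @return A `group_set` with 22 groups.
#' @examples
#' gs <- default_group_set()
#' group_names(gs)
#' @export
default_group_set <- function() {
  if (is.null(the$default_gs)) {
    path <- system.file("extdata", "diagnostic_groups.yaml", package = "caselogr")
    the$default_gs <- read_group_set(path)
  }
  the$default_gs
}

#' @export
print.group_set <- function(x, ...) {
  cat(sprintf("<group_set %s: %d groups, %d patterns>\n", x$version,
              length(x$groups), sum(map_int(x$groups, ~ length(.x$patterns)))))
  invisible(x)
}

#' Group names of a group set, in definition order
#' @param group_set A `group_set`.
#' @export
group_names <- function(group_set) {
  stopifnot(inherits(group_set, "group_set"))
  unname(map_chr(group_set$groups, "name"))
}

#' @describeIn read_group_set Tidy a compiled `group_set` into one row per
#'   pattern with columns `group`, `token`, `kind`, `stem`, `low`, `high`
#'   and `notes`.
#' @param x A `group_set`.
#' @param ... Unused.
#' @method tidy group_set
#' @export
tidy.group_set <- function(x, ...) {
  map(x$groups, function(g) {
    tibble(
      group = g$name,
      token = map_chr(g$patterns, "source_text"),
      kind  = map_chr(g$patterns, "kind"),
      stem  = map_chr(g$patterns, "stem"),
      low   = map_chr(g$patterns, "low"),
      high  = map_chr(g$patterns, "high"),
      notes = g$notes
    )
  }) |> list_rbind()
}

# membership of each unique code in each group: tibble(code, group),
# one row per (code, group) hit; codes must already be normalized
match_group_table <- function(codes, group_set) {
  stopifnot(inherits(group_set, "group_set"))
  ucodes <- unique(codes)
  if (length(ucodes) == 0) {
    return(tibble(code = character(), group = character()))
  }
  map(group_set$groups, function(g) {
    hit <- rep(FALSE, length(ucodes))
    for (p in g$patterns) hit <- hit | code_matches(p, ucodes)
    tibble(code = ucodes[hit], group = g$name)
  }) |> list_rbind()
}

#' Assign normalized codes to diagnostic groups
#'
#' Every group with at least one matching pattern is returned for each
#' code; a code may belong to several groups, and a code matched by no
#' group yields an empty set (the pipeline later tallies such codes as
#' unmapped rather than erroring, since curated sets exclude common
#' self-limited diagnoses on purpose).
#'
#' @param codes Character vector of normalized codes.
#' @param group_set A `group_set`.
#' @return A named list, one character vector of group names per code.
#' @examples
#' assign_groups(c("Z00129", "J069"), default_group_set())
#' @export
assign_groups <- function(codes, group_set) {
  hits <- match_group_table(codes, group_set)
  out <- map(set_names_safely(codes), function(cd) hits$group[hits$code == cd])
  out
}

set_names_safely <- function(x) setNames(x, x)

#' Audit a group set for overlaps and dead groups
#'
#' Evaluates every group against a finite universe of codes and reports
#' (a) each universe code claimed by two or more groups and (b) each group
#' matched by no universe code. By default the universe is generated from
#' the set's own patterns via [enumerate_samples()], which is enough to
#' surface inter-group overlaps among the codes the set itself targets.
#'
#' @param group_set A `group_set`.
#' @param universe Optional character vector of normalized codes; defaults
#'   to samples enumerated from the set's own patterns.
#' @param samples_per_pattern Samples drawn per pattern when building the
#'   default universe.
#' @return A list with `overlaps` (tibble: `code`, `n_groups`, `groups`)
#'   and `unmatched_groups` (character vector).
#' @export
validate_group_set <- function(group_set, universe = NULL,
                               samples_per_pattern = 10) {
  stopifnot(inherits(group_set, "group_set"))
  if (is.null(universe)) {
    universe <- unique(unlist(map(group_set$groups, function(g) {
      unlist(map(g$patterns, enumerate_samples, k = samples_per_pattern))
    })))
  }
  hits <- match_group_table(universe, group_set)
  overlaps <- hits |>
    summarise(n_groups = n(), groups = list(sort(.data$group)), .by = "code") |>
    filter(.data$n_groups >= 2) |>
    arrange(.data$code)
  unmatched <- setdiff(group_names(group_set), unique(hits$group))
  list(overlaps = overlaps, unmatched_groups = unmatched)
}
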