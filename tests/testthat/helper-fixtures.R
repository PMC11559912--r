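# Shared fixtures and the independent matcher oracle.

# Brute-force membership test, written by explicit case analysis and kept
# independent of code_matches(): a code is in a range iff it sorts at or
# after the low endpoint and either sorts at or before the high endpoint
# or extends it (subcodes of the high category belong to the range).
oracle_matches <- function(pattern, codes) {
  switch(pattern$kind,
    EXACT = codes == pattern$stem,
    PREFIX = substr(codes, 1, nchar(pattern$stem)) == pattern$stem,
    RANGE = codes >= pattern$low &
      (codes <= pattern$high |
         substr(codes, 1, nchar(pattern$high)) == pattern$high)
  )
}

# every grammar-valid code of length <= 5 over the restricted alphabet:
# the given letter plus digits 0-9
code_universe <- function(letter) {
  alpha <- c(as.character(0:9), letter)
  l3 <- paste0(letter, sprintf("%02d", 0:99))
  l4 <- as.vector(outer(l3, alpha, paste0))
  l5 <- as.vector(outer(l4, alpha, paste0))
  c(l3, l4, l5)
}

# published sample column: one PGY2 resident's unique-visit counts, in the
# shipped group order, with the matching class and graduate averages
benchmark_column_fixture <- function() {
  tibble::tibble(
    group = group_names(default_group_set()),
    individual = c(463, 5, 32, 9, 51, 7, 23, 69, 0, 18, 26, 16, 15, 0, 33,
                   5, 0, 3, 1, 1, 0, 10),
    class_mean = c(454, 7, 33, 9, 17, 4, 14, 79, 3, 25, 28, 11, 11, 2, 24,
                   9, 8, 8, 3, 7, 10, 19),
    graduate_mean = c(863, 11, 54, 13, 28, 4, 20, 104, 6, 58, 47, 24, 25,
                      3, 54, 15, 8, 16, 5, 10, 4, 38)
  )
}

# roster matching the reference class sizes
fixture_roster <- function(class_sizes = ref_class_sizes()) {
  purrr::pmap(class_sizes, function(class_year, n) {
    tibble::tibble(resident_id = sprintf("R%d_%02d", class_year, seq_len(n)),
                   class_year = as.integer(class_year))
  }) |> purrr::list_rbind()
}

# write an encounters CSV from raw text rows (header added)
write_enc_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("encounter_id,resident_id,patient_id,service_date,diagnoses",
               rows), path)
  path
}

write_roster_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path, progress = FALSE)
  path
}

# compile a throwaway group set from name -> token-vector pairs
make_group_set <- function(..., version = "test") {
  defs <- list(...)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(
    list(version = version,
         groups = unname(purrr::imap(defs,
                                     ~ list(name = .y, codes = as.list(.x))))),
    path)
  read_group_set(path)
}

# a small, fast simulation: two graduate classes, scaled-down rates
small_sim_config <- function(seed = 1, ...) {
  sim_config(
    seed = seed,
    class_sizes = tibble::tibble(class_year = c(2018L, 2019L, 2021L),
                                 n = c(5L, 5L, 4L)),
    group_rates = default_group_rates() |>
      dplyr::mutate(rate = rate / 10),
    ...
  )
}

# build a volume_matrix by hand from a counts tibble (resident_id, group,
# count), for tests that need full control of the cells
manual_matrix <- function(counts, group_order = unique(counts$group),
                          as_of = as.Date("2020-04-01")) {
  residents <- unique(counts$resident_id)
  out <- tidyr::crossing(resident_id = residents, group = group_order) |>
    dplyr::left_join(counts, by = c("resident_id", "group")) |>
    dplyr::mutate(count = tidyr::replace_na(count, 0),
                  group = factor(group, levels = group_order)) |>
    dplyr::arrange(resident_id, group) |>
    dplyr::mutate(group = as.character(group))
  structure(out, class = c("volume_matrix", class(out)),
            group_order = group_order, n_unmapped = 0L, as_of = as_of)
}
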