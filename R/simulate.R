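# Synthetic EHR encounter generator. Emulates the encounter stream the
# pipeline was designed for: seven residency classes of published sizes,
# per-group annual visit rates rising with PGY level, multi-diagnosis
# well-check encounters, and a configurable share of encounters carrying
# codes that map to no curated group (standing in for the common
# self-limited diagnoses a curated set deliberately omits).

#' Reference class sizes
#'
#' Class sizes of the seven-cohort pilot roster: classes 2016-2022 with
#' 8, 15, 18, 11, 18, 19 and 13 residents (102 in all; the four earliest
#' classes, 52 residents, form the graduate benchmark).
#'
#' @return Tibble with `class_year` and `n`.
#' @export
ref_class_sizes <- function() {
  tibble(class_year = 2016:2022, n = c(8L, 15L, 18L, 11L, 18L, 19L, 13L))
}

#' Reference cumulative benchmark targets
#'
#' Published per-group average cumulative unique-visit counts at the end
#' of PGY1, end of PGY2, and graduation, used to calibrate the generator.
#'
#' @return Tibble with `group`, `pgy1`, `pgy2`, `graduate`.
#' @export
ref_benchmark_targets <- function() {
  tribble(
    ~group, ~pgy1, ~pgy2, ~graduate,
    "Well check", 150, 454, 863,
    "Anemia", 2, 7, 11,
    "Constipation", 11, 33, 54,
    "Vomiting/diarrhea", 3, 9, 13,
    "Underweight/failure to thrive", 5, 17, 28,
    "Gait problem/limp", 3, 4, 4,
    "Genitourinary concerns", 4, 14, 20,
    "Overweight/obesity, increased BMI", 27, 79, 104,
    "Sexually transmitted infections", 2, 3, 6,
    "Asthma", 10, 25, 58,
    "Eczema", 9, 28, 47,
    "Heart murmurs", 7, 11, 24,
    "Ear infections", 4, 11, 25,
    "Urinary tract infection", 2, 2, 3,
    "Developmental delay", 8, 24, 54,
    "Behavioral/ADHD", 4, 9, 15,
    "Young women’s health", 3, 8, 8,
    "Headache", 3, 8, 16,
    "Autism spectrum disorder", 2, 3, 5,
    "Genetic and chromosomal disorders", 3, 7, 10,
    "Specific congenital nongenetic disorders", 3, 10, 4,
    "Vaccine hesitancy", 7, 19, 38
  )
}

#' Annual visit rates calibrated to the reference targets
#'
#' Converts the cumulative targets of [ref_benchmark_targets()] into
#' annual Poisson rates by successive differencing, so expected cumulative
#' counts reproduce the PGY1 / PGY2 / graduate columns (well check:
#' 150, 304, 409 per year). One published row (specific congenital
#' nongenetic disorders) has a graduate mean below the PGY2 class mean —
#' the two columns average different cohorts — which would difference to a
#' negative rate; negative increments are clamped to zero, so that group's
#' configured graduate expectation telescopes above its printed value.
#'
#' @return Tibble with `group`, `pgy_year` (1-3) and `rate` (expected
#'   qualifying visits per academic year).
#' @export
default_group_rates <- function() {
  t <- ref_benchmark_targets()
  tibble(
    group = rep(t$group, each = 3),
    pgy_year = rep(1:3, times = nrow(t)),
    rate = pmax(0, as.vector(rbind(t$pgy1, t$pgy2 - t$pgy1,
                                   t$graduate - t$pgy2)))
  )
}

#' Simulation configuration
#'
#' Defaults reproduce the pilot's study conditions: the seven reference
#' class sizes, rates calibrated to the published benchmark columns, data
#' extraction as of 2020-04-01, a 3-year program on a July-June calendar.
#'
#' @param seed Integer RNG seed.
#' @param class_sizes Tibble `class_year`, `n` (default
#'   [ref_class_sizes()]).
#' @param group_rates Tibble `group`, `pgy_year`, `rate` (default
#'   [default_group_rates()]).
#' @param wellcheck_comorbidity Probability that a qualifying non-well-check
#'   diagnosis is coded on one of the resident's existing well-check
#'   encounters from the same academic year instead of its own visit
#'   (default 0.2), exercising multi-group encounters.
#' @param noise_frac Expected unmapped-code encounters as a fraction of a
#'   resident's qualifying visit rate (default 0.2).
#' @param as_of Extraction cutoff date.
#' @param program_length Years of training (default 3).
#' @param calendar An [academic_calendar()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       class_sizes = ref_class_sizes(),
                       group_rates = default_group_rates(),
                       wellcheck_comorbidity = 0.2,
                       noise_frac = 0.2,
                       as_of = "2020-04-01",
                       program_length = 3L,
                       calendar = academic_calendar()) {
  if (any(group_rates$rate < 0)) {
    abort("Rates must be non-negative", class = "caselogr_bad_config")
  }
  if (wellcheck_comorbidity < 0 || wellcheck_comorbidity > 1 ||
      noise_frac < 0) {
    abort("Probabilities must lie in [0, 1] and noise_frac must be >= 0",
          class = "caselogr_bad_config")
  }
  if (any(class_sizes$n < 0)) {
    abort("Class sizes must be non-negative", class = "caselogr_bad_config")
  }
  structure(
    list(seed = as.integer(seed), class_sizes = class_sizes,
         group_rates = group_rates,
         wellcheck_comorbidity = wellcheck_comorbidity,
         noise_frac = noise_frac, as_of = as.Date(as_of),
         program_length = as.integer(program_length), calendar = calendar),
    class = "sim_config"
  )
}

# per (class_year, pgy_year): academic-year span clipped at as_of, and the
# elapsed fraction of that year
year_spans <- function(config) {
  tidyr::crossing(class_year = config$class_sizes$class_year,
                  pgy_year = seq_len(config$program_length)) |>
    mutate(
      start_year = .data$class_year - .env$config$program_length +
        .data$pgy_year - 1L,
      ay_start = as.Date(sprintf("%d-%02d-%02d", .data$start_year,
                                 config$calendar$start_month,
                                 config$calendar$start_day)),
      ay_end = as.Date(sprintf("%d-%02d-%02d", .data$start_year + 1L,
                               config$calendar$start_month,
                               config$calendar$start_day)) - 1L,
      eff_end = pmin(.data$ay_end, .env$config$as_of),
      frac = as.numeric(.data$eff_end - .data$ay_start + 1) /
        as.numeric(.data$ay_end - .data$ay_start + 1)
    ) |>
    filter(.data$eff_end >= .data$ay_start) |>
    select("class_year", "pgy_year", "ay_start", "eff_end", "frac")
}

#' Expected cumulative counts implied by a configuration
#'
#' Per class and group, the expected unique-visit count accumulated by the
#' extraction date: the sum over elapsed academic years of rate x elapsed
#' fraction. This is the ground truth the recovery harness checks
#' estimates against.
#'
#' @param config A [sim_config()].
#' @return Tibble `class_year`, `group`, `expected`.
#' @export
expected_counts <- function(config) {
  year_spans(config) |>
    inner_join(config$group_rates, by = "pgy_year",
               relationship = "many-to-many") |>
    summarise(expected = sum(.data$rate * .data$frac),
              .by = c("class_year", "group"))
}

# codes usable as unmapped noise (verified against the group set at run
# time): common self-limited outpatient diagnoses
noise_pool <- function(group_set) {
  cand <- c("J069", "J00", "J029", "J039", "B349", "R509", "L229", "H109",
            "J111", "R05")
  hits <- match_group_table(cand, group_set)
  pool <- setdiff(cand, hits$code)
  if (length(pool) == 0) {
    abort("No unmapped noise codes available for this group set",
          class = "caselogr_bad_config")
  }
  pool
}

# per-group code pools drawn from the set's own patterns, restricted to
# codes that map back to exactly that one group
group_code_pools <- function(group_set, k = 6) {
  pools <- map(group_set$groups, function(g) {
    codes <- unique(unlist(map(g$patterns, enumerate_samples, k = k)))
    memb <- match_group_table(codes, group_set)
    solo <- memb |> count(.data$code) |> filter(.data$n == 1)
    keep <- intersect(codes, solo$code)
    if (length(keep) > 0) keep else codes
  })
  setNames(pools, group_names(group_set))
}

#' Simulate a synthetic encounter stream
#'
#' Per resident, academic year and group, draws a Poisson number of
#' qualifying visits at the configured annual rate (scaled by the elapsed
#' fraction of years cut by the extraction date), dates them uniformly
#' within the year, and assigns each visit one ICD-10 code enumerated from
#' the group's own patterns. With probability `wellcheck_comorbidity` a
#' non-well-check diagnosis is attached to one of the resident's existing
#' well-check encounters from the same year, producing multi-group visits.
#' Additional encounters carrying unmapped codes are layered on at
#' `noise_frac` of the qualifying rate. A truth table of realized
#' per-resident per-group unique-visit counts is recorded from the
#' generation bookkeeping itself.
#'
#' @param config A [sim_config()].
#' @param group_set A `group_set` (default the shipped pediatric set).
#' @return A `caselog_sim`: list with `roster`, `encounters` (same shape
#'   as [read_encounters()] output), `truth` (tibble `resident_id`,
#'   `group`, `count`) and `config`.
#' @export
simulate_encounters <- function(config, group_set = default_group_set()) {
  stopifnot(inherits(config, "sim_config"))
  extra <- setdiff(unique(config$group_rates$group), group_names(group_set))
  if (length(extra) > 0) {
    abort(sprintf("Rates reference unknown group(s): %s",
                  paste(extra, collapse = ", ")),
          class = "caselogr_bad_config")
  }

  roster <- config$class_sizes |>
    filter(.data$n > 0) |>
    pmap(function(class_year, n) {
      tibble(resident_id = sprintf("R%d_%02d", class_year, seq_len(n)),
             class_year = as.integer(class_year))
    }) |>
    list_rbind()

  pools <- group_code_pools(group_set)
  npool <- noise_pool(group_set)
  spans <- year_spans(config)
  gnames <- group_names(group_set)

  sim <- with_private_seed(config$seed, {
    cells <- roster |>
      inner_join(spans, by = "class_year",
                 relationship = "many-to-many") |>
      inner_join(config$group_rates, by = "pgy_year",
                 relationship = "many-to-many") |>
      mutate(n_visits = rpois(n(), .data$rate * .data$frac))

    visits <- cells |>
      filter(.data$n_visits > 0) |>
      tidyr::uncount(weights = .data$n_visits) |>
      mutate(
        span_days = as.numeric(.data$eff_end - .data$ay_start) + 1,
        service_date = .data$ay_start +
          floor(runif(n()) * .data$span_days),
        code = NA_character_
      )
    # deterministic per-group code draws
    visits <- visits |>
      group_by(.data$group) |>
      mutate(code = sample(pools[[.data$group[1]]], n(), replace = TRUE)) |>
      ungroup()

    wc <- visits |> filter(.data$group == "Well check") |>
      mutate(encounter_id = sprintf("W%06d", row_number()))
    others <- visits |> filter(.data$group != "Well check") |>
      mutate(try_attach = runif(n()) < config$wellcheck_comorbidity)

    wc_lookup <- wc |>
      summarise(wc_ids = list(.data$encounter_id),
                wc_dates = list(.data$service_date),
                .by = c("resident_id", "pgy_year"))
    others <- others |>
      left_join(wc_lookup, by = c("resident_id", "pgy_year")) |>
      mutate(encounter_id = sprintf("V%06d", row_number()))
    attachable <- which(others$try_attach &
                          lengths(others$wc_ids) > 0)
    if (length(attachable) > 0) {
      picks <- map_int(others$wc_ids[attachable],
                       ~ sample.int(length(.x), 1))
      others$encounter_id[attachable] <- map2_chr(
        others$wc_ids[attachable], picks, ~ .x[[.y]])
      others$service_date[attachable] <- as.Date(map2_dbl(
        others$wc_dates[attachable], picks, ~ as.numeric(.x[[.y]])))
    }
    others <- others |> select(-"wc_ids", -"wc_dates", -"try_attach")

    qualifying <- bind_rows(
      wc |> select("resident_id", "group", "encounter_id", "service_date",
                   "code"),
      others |> select("resident_id", "group", "encounter_id",
                       "service_date", "code")
    )

    # unmapped-noise encounters at noise_frac of the qualifying rate
    noise <- roster |>
      inner_join(spans, by = "class_year",
                 relationship = "many-to-many") |>
      inner_join(
        config$group_rates |> summarise(total = sum(.data$rate),
                                        .by = "pgy_year"),
        by = "pgy_year") |>
      mutate(n_visits = rpois(n(), config$noise_frac * .data$total *
                                .data$frac)) |>
      filter(.data$n_visits > 0) |>
      tidyr::uncount(weights = .data$n_visits) |>
      mutate(
        span_days = as.numeric(.data$eff_end - .data$ay_start) + 1,
        service_date = .data$ay_start + floor(runif(n()) * .data$span_days),
        encounter_id = sprintf("N%06d", row_number()),
        code = sample(npool, n(), replace = TRUE),
        group = NA_character_
      ) |>
      select("resident_id", "group", "encounter_id", "service_date", "code")

    all_rows <- bind_rows(qualifying, noise)
    # most encounters carry one code; only attachment-merged ones need a
    # set union, so split the work for speed
    is_dup <- all_rows$encounter_id %in%
      all_rows$encounter_id[duplicated(all_rows$encounter_id)]
    singles <- all_rows[!is_dup, ] |>
      mutate(diagnoses = as.list(.data$code))
    merged <- all_rows[is_dup, ] |>
      summarise(
        resident_id = .data$resident_id[1],
        service_date = .data$service_date[1],
        diagnoses = list(sort(unique(.data$code))),
        .by = "encounter_id"
      )
    encounters <- bind_rows(
      singles |> select("encounter_id", "resident_id", "service_date",
                        "diagnoses"),
      merged
    ) |>
      arrange(.data$encounter_id) |>
      mutate(patient_id = sprintf("%s-P%03d", .data$resident_id,
                                  sample.int(200L, n(), replace = TRUE))) |>
      select("encounter_id", "resident_id", "patient_id", "service_date",
             "diagnoses")

    truth <- qualifying |>
      distinct(.data$resident_id, .data$group, .data$encounter_id) |>
      count(.data$resident_id, .data$group, name = "count") |>
      right_join(tidyr::crossing(resident_id = roster$resident_id,
                                 group = gnames),
                 by = c("resident_id", "group")) |>
      mutate(count = tidyr::replace_na(.data$count, 0L)) |>
      arrange(.data$resident_id,
              factor(.data$group, levels = gnames))

    list(encounters = encounters, truth = truth)
  })

  structure(
    list(roster = roster, encounters = sim$encounters, truth = sim$truth,
         config = config),
    class = "caselog_sim"
  )
}

#' @export
print.caselog_sim <- function(x, ...) {
  cat(sprintf("<caselog_sim: %d residents, %d encounters, seed %d>\n",
              nrow(x$roster), nrow(x$encounters), x$config$seed))
  invisible(x)
}

#' Write a simulation to flat files
#'
#' Emits `roster.csv`, `encounters.csv` (the dialect [read_encounters()]
#' reads) and `truth.csv` under `dir`. Rerunning with the same config and
#' seed produces byte-identical files.
#'
#' @param sim A `caselog_sim`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_sim_output <- function(sim, dir) {
  stopifnot(inherits(sim, "caselog_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    roster = file.path(dir, "roster.csv"),
    encounters = file.path(dir, "encounters.csv"),
    truth = file.path(dir, "truth.csv")
  )
  readr::write_csv(sim$roster, paths[["roster"]], progress = FALSE)
  write_encounters(sim$encounters, paths[["encounters"]])
  readr::write_csv(sim$truth, paths[["truth"]], progress = FALSE)
  invisible(paths)
}

#' Check pipeline estimates against configured expectations
#'
#' Runs the counting pipeline on a simulation and compares each cohort's
#' per-group mean against the expectation implied by the configuration,
#' with z-scores under the Poisson standard error `sqrt(mu / n)`.
#'
#' @param sim A `caselog_sim`.
#' @param benchmark_classes Classes forming the graduate benchmark
#'   (default: all classes fully graduated by the sim's as-of date).
#' @param group_set The `group_set` used to generate the sim.
#' @return Tibble with `cohort`, `group`, `n`, `expected`, `estimated`,
#'   `z` (NA where the expectation is zero) and `within_3se`.
#' @export
recover_parameters <- function(sim, benchmark_classes = NULL,
                               group_set = default_group_set()) {
  stopifnot(inherits(sim, "caselog_sim"))
  cfg0 <- sim$config
  if (is.null(benchmark_classes)) {
    lvl <- pgy_level(cfg0$class_sizes$class_year, cfg0$as_of, cfg0$calendar,
                     cfg0$program_length)
    benchmark_classes <- cfg0$class_sizes$class_year[lvl == "GRADUATED"]
  }
  cfg <- cohort_config(cfg0$as_of, benchmark_classes,
                       program_length = cfg0$program_length,
                       calendar = cfg0$calendar)
  ds <- link_dataset(sim$encounters, sim$roster, mode = "strict")
  vm <- count_volumes(ds, group_set, cfg)
  part <- partition_roster(sim$roster, cfg)
  bm <- build_benchmarks(vm, part)

  exp_tbl <- expected_counts(cfg0)
  grad_exp <- exp_tbl |>
    filter(.data$class_year %in% benchmark_classes) |>
    inner_join(cfg0$class_sizes, by = "class_year") |>
    summarise(expected = sum(.data$expected * .data$n) / sum(.data$n),
              .by = "group")
  grad <- bm$graduate |>
    inner_join(grad_exp, by = "group") |>
    mutate(cohort = "graduate", n = nrow(part$graduates))

  cls <- bm$classes |>
    inner_join(exp_tbl, by = c("class_year", "group")) |>
    inner_join(cfg0$class_sizes, by = "class_year") |>
    mutate(cohort = as.character(.data$class_year)) |>
    select("cohort", "group", "mean", "expected", "n")

  bind_rows(grad |> select("cohort", "group", "mean", "expected", "n"),
            cls) |>
    mutate(
      estimated = .data$mean,
      z = ifelse(.data$expected > 0,
                 (.data$estimated - .data$expected) /
                   sqrt(.data$expected / .data$n),
                 NA_real_),
      within_3se = is.na(.data$z) | abs(.data$z) <= 3
    ) |>
    select("cohort", "group", "n", "expected", "estimated", "z",
           "within_3se")
}
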