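make_linked <- function(rows, roster) {
  link_dataset(read_encounters(write_enc_csv(rows)), roster, "strict")
}

two_group_set <- function() {
  make_group_set(`Well check` = c("Z00.129", "Z00.121"),
                 Constipation = "K59.xx")
}

test_that("volume counts unique visits, once per group per encounter", {
  roster <- tibble::tibble(resident_id = "R1", class_year = 2021L)
  cfg <- cohort_config("2020-04-01", 2016:2019)
  gs <- two_group_set()

  # one encounter, codes in two groups: counts once in each
  ds <- make_linked("E1,R1,P1,2019-10-02,Z00.129;K59.00", roster)
  vm <- count_volumes(ds, gs, cfg)
  expect_equal(vm$count[vm$group == "Well check"], 1L)
  expect_equal(vm$count[vm$group == "Constipation"], 1L)

  # two codes of the same group on one encounter: still one visit
  ds2 <- make_linked("E1,R1,P1,2019-10-02,K59.00;K59.09", roster)
  vm2 <- count_volumes(ds2, gs, cfg)
  expect_equal(vm2$count[vm2$group == "Constipation"], 1L)

  # visits, not patients: same patient twice counts twice
  ds3 <- make_linked(c("E1,R1,P1,2019-10-02,K59.00",
                       "E2,R1,P1,2019-11-02,K59.00"), roster)
  vm3 <- count_volumes(ds3, gs, cfg)
  expect_equal(vm3$count[vm3$group == "Constipation"], 2L)

  # encounters after the as-of date or outside the window contribute zero
  ds4 <- make_linked(c("E1,R1,P1,2020-04-02,K59.00",
                       "E2,R1,P1,2018-06-30,K59.00"), roster)
  vm4 <- count_volumes(ds4, gs, cfg)
  expect_equal(sum(vm4$count), 0L)

  # unmapped codes are tallied, not counted
  ds5 <- make_linked("E1,R1,P1,2019-10-02,J06.9;K59.00", roster)
  vm5 <- count_volumes(ds5, gs, cfg)
  expect_equal(attr(vm5, "n_unmapped"), 1L)
  expect_equal(sum(vm5$count), 1L)
})

test_that("volume counts are invariant to encounter row order", {
  rows <- c("E1,R1,P1,2019-10-02,Z00.129;K59.00",
            "E2,R1,P2,2019-11-02,K59.00",
            "E3,R2,P3,2019-12-02,Z00.121",
            "E4,R2,P4,2020-01-02,K59.09")
  roster <- tibble::tibble(resident_id = c("R1", "R2"),
                           class_year = c(2021L, 2022L))
  cfg <- cohort_config("2020-04-01", 2016:2019)
  gs <- two_group_set()
  base <- count_volumes(make_linked(rows, roster), gs, cfg)
  for (perm in list(c(4, 2, 3, 1), c(2, 1, 4, 3), 4:1)) {
    shuffled <- count_volumes(make_linked(rows[perm], roster), gs, cfg)
    expect_equal(tibble::as_tibble(shuffled), tibble::as_tibble(base))
  }
})

test_that("variety counts groups seen at least once", {
  t3 <- benchmark_column_fixture()
  vm <- manual_matrix(tibble::tibble(resident_id = "R1", group = t3$group,
                                     count = t3$individual),
                      group_order = t3$group)
  expect_equal(variety(vm, "R1"), sum(t3$individual > 0))
  expect_equal(variety(vm, "R1"), 18L)
  vm0 <- manual_matrix(tibble::tibble(resident_id = "R0",
                                      group = t3$group, count = 0),
                       group_order = t3$group)
  expect_equal(variety(vm0, "R0"), 0L)
  expect_error(variety(vm, "nobody"), class = "caselogr_unknown_resident")
})

test_that("cohort means include zero-count members at full precision", {
  counts <- tibble::tibble(resident_id = c("a", "b"), group = "Asthma",
                           count = c(4, 0))
  vm <- manual_matrix(counts)
  expect_equal(cohort_mean(vm, c("a", "b"))$mean, 2.0)
  expect_equal(cohort_mean(vm, "a")$mean, 4.0)
  expect_error(cohort_mean(vm, character()), class = "caselogr_empty_cohort")
  expect_error(cohort_mean(vm, "zz"), class = "caselogr_unknown_resident")
})

test_that("merged-cohort mean is the size-weighted mean of subcohorts", {
  set.seed(99)
  counts <- tidyr::crossing(resident_id = sprintf("r%02d", 1:9),
                            group = c("g1", "g2")) |>
    dplyr::mutate(count = rpois(dplyr::n(), 6))
  vm <- manual_matrix(counts, group_order = c("g1", "g2"))
  a <- sprintf("r%02d", 1:4)
  b <- sprintf("r%02d", 5:9)
  merged <- cohort_mean(vm, c(a, b))
  weighted <- (4 * cohort_mean(vm, a)$mean + 5 * cohort_mean(vm, b)$mean) / 9
  expect_equal(merged$mean, weighted)
})

test_that("graduate-mean estimates are unbiased under Poisson sampling", {
  # 30 synthetic graduates with one diagnostic group at 11 expected
  # qualifying visits over three years
  rates <- tibble::tibble(group = "Anemia", pgy_year = 1:3,
                          rate = c(2, 5, 4))
  cfg <- sim_config(seed = 7,
                    class_sizes = tibble::tibble(class_year = 2019L, n = 30L),
                    group_rates = rates, noise_frac = 0,
                    wellcheck_comorbidity = 0)
  sim <- simulate_encounters(cfg)
  ds <- link_dataset(sim$encounters, sim$roster, "strict")
  vm <- count_volumes(ds, default_group_set(),
                      cohort_config("2020-04-01", 2019L))
  m <- cohort_mean(vm, sim$roster$resident_id)
  est <- m$mean[m$group == "Anemia"]
  expect_lt(abs(est - 11), 3 * sqrt(11 / 30))
})

test_that("percent-of-benchmark normalization handles identity, excess and zero", {
  expect_equal(percent_of_benchmark(463, 863), 100 * 463 / 863)
  expect_equal(round(percent_of_benchmark(463, 863), 2), 53.65)
  expect_equal(percent_of_benchmark(863, 863), 100)
  expect_equal(percent_of_benchmark(10, 4), 250)
  expect_true(is.na(percent_of_benchmark(5, 0)))
  expect_equal(percent_of_benchmark(0, 37), 0)
  expect_error(percent_of_benchmark(-1, 5))
})

test_that("benchmark tables hold graduate and per-class means", {
  t3 <- benchmark_column_fixture()
  roster <- tibble::tibble(
    resident_id = c("g1", "g2", "a1"),
    class_year = c(2019L, 2019L, 2021L)
  )
  counts <- dplyr::bind_rows(
    tibble::tibble(resident_id = "g1", group = t3$group,
                   count = t3$graduate_mean),
    tibble::tibble(resident_id = "g2", group = t3$group,
                   count = t3$graduate_mean),
    tibble::tibble(resident_id = "a1", group = t3$group,
                   count = t3$individual)
  )
  vm <- manual_matrix(counts, group_order = t3$group)
  part <- partition_roster(roster, cohort_config("2020-04-01", 2019L))
  bm <- build_benchmarks(vm, part)
  expect_equal(bm$graduate$mean, t3$graduate_mean)
  expect_equal(bm$classes$mean, t3$individual)
  expect_equal(glance(bm)$n_graduates, 2L)

  td <- tidy(bm)
  expect_setequal(unique(td$cohort), c("graduate", "2021"))
  expect_equal(td$display, round(td$mean + 1e-9))  # integers here

  # single-graduate benchmark equals that resident's counts
  solo <- partition_roster(roster[c(1, 3), ],
                           cohort_config("2020-04-01", 2019L))
  expect_equal(build_benchmarks(vm, solo)$graduate$mean, t3$graduate_mean)

  # all-zero matrix gives all-zero means
  vz <- manual_matrix(tibble::tibble(resident_id = c("g1", "g2", "a1"),
                                     group = "Asthma", count = 0))
  expect_equal(sum(build_benchmarks(vz, part)$graduate$mean), 0)
})

test_that("a resident's cell never exceeds their unique encounter total", {
  sim <- simulate_encounters(small_sim_config(seed = 5))
  ds <- link_dataset(sim$encounters, sim$roster, "strict")
  cfg <- cohort_config(sim$config$as_of, c(2018L, 2019L))
  vm <- count_volumes(ds, default_group_set(), cfg)
  totals <- sim$encounters |> dplyr::count(resident_id, name = "n_enc")
  joined <- tibble::as_tibble(vm) |>
    dplyr::left_join(totals, by = "resident_id") |>
    dplyr::mutate(n_enc = tidyr::replace_na(n_enc, 0L))
  expect_true(all(joined$count <= joined$n_enc))
})
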