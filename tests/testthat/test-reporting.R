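# shared fixture: a tiny run with two graduates and two active residents
report_fixture <- function() {
  t3 <- benchmark_column_fixture()
  roster <- tibble::tibble(
    resident_id = c("g1", "g2", "a1", "a2"),
    class_year = c(2019L, 2019L, 2021L, 2021L)
  )
  counts <- dplyr::bind_rows(
    tibble::tibble(resident_id = "g1", group = t3$group,
                   count = t3$graduate_mean),
    tibble::tibble(resident_id = "g2", group = t3$group,
                   count = t3$graduate_mean),
    tibble::tibble(resident_id = "a1", group = t3$group,
                   count = t3$individual),
    tibble::tibble(resident_id = "a2", group = t3$group,
                   count = pmax(0, 2 * t3$class_mean - t3$individual))
  )
  vm <- manual_matrix(counts, group_order = t3$group)
  part <- partition_roster(roster, cohort_config("2020-04-01", 2019L))
  list(t3 = t3, vm = vm, bm = build_benchmarks(vm, part))
}

test_that("category order is a deterministic seeded shuffle", {
  nms <- group_names(default_group_set())
  expect_identical(order_categories(nms, 0), order_categories(nms, 0))
  expect_false(identical(order_categories(nms, 0), order_categories(nms, 1)))
  expect_setequal(order_categories(nms, 3), nms)
  expect_identical(order_categories("solo", 5), "solo")
  # the shuffle leaves the caller's RNG stream untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(order_categories(nms, 0)); after <- runif(1)
  expect_identical(before, after)
})

test_that("individual reports align counts with class and graduate benchmarks", {
  fx <- report_fixture()
  rep <- build_individual_report("a1", fx$vm, fx$bm, order_seed = 4)
  expect_equal(nrow(rep), 22)  # every group present, zeros included
  yw <- rep[rep$group == "Young women’s health", ]
  expect_equal(yw$count, 0)
  expect_equal(yw$class_mean, 8)
  expect_equal(yw$graduate_mean, 8)
  expect_equal(yw$pct_graduate, 0)
  wc <- rep[rep$group == "Well check", ]
  expect_equal(wc$count, 463)
  expect_equal(round(wc$pct_graduate, 2), 53.65)
  expect_equal(attr(rep, "variety"), 18L)
  expect_equal(attr(rep, "pgy"), "PGY2")

  expect_error(build_individual_report("g1", fx$vm, fx$bm),
               class = "caselogr_graduated_resident")
  expect_error(build_individual_report("nobody", fx$vm, fx$bm),
               class = "caselogr_unknown_resident")
})

test_that("class reports carry one series per active class", {
  fx <- report_fixture()
  crep <- build_class_report(fx$vm, fx$bm, order_seed = 4)
  wc <- crep[crep$group == "Well check", ]
  expect_equal(wc$class_mean, 454)
  expect_equal(wc$graduate_mean, 863)
  radar <- attr(crep, "radar")
  expect_named(radar$series, c("PGY2", "graduate"))

  empty_part <- partition_roster(
    tibble::tibble(resident_id = c("g1", "g2"), class_year = 2019L),
    cohort_config("2020-04-01", 2019L))
  bm2 <- build_benchmarks(fx$vm, empty_part)
  expect_error(build_class_report(fx$vm, bm2),
               class = "caselogr_empty_cohort")
})

test_that("radar specs mirror report numbers exactly and at true scale", {
  fx <- report_fixture()
  rep <- build_individual_report("a1", fx$vm, fx$bm, order_seed = 9)
  radar <- attr(rep, "radar")
  # chart-data fidelity: series values equal the table's percents
  expect_equal(radar$series$individual[rep$group],
               setNames(rep$pct_graduate, rep$group))
  # graduate self-profile is the 100% ring wherever defined
  expect_true(all(radar$series$graduate[!is.na(radar$series$graduate)] == 100))
  # every group appears exactly once
  expect_setequal(radar$categories, rep$group)
  expect_equal(anyDuplicated(radar$categories), 0L)

  # a 250% cell pushes the axis beyond the 100 ring
  part <- fx$bm$partition
  counts <- tibble::tibble(resident_id = c("g1", "g2", "a1", "a2"),
                           group = "Asthma", count = c(4, 4, 10, 2))
  vm <- manual_matrix(counts)
  bm <- build_benchmarks(vm, part)
  rep2 <- build_individual_report("a1", vm, bm)
  expect_equal(rep2$pct_graduate, 250)
  expect_gte(attr(rep2, "radar")$axis_max, 250)
})

test_that("category order is shared across all charts of one batch", {
  fx <- report_fixture()
  seed <- 11
  r1 <- build_individual_report("a1", fx$vm, fx$bm, order_seed = seed)
  r2 <- build_individual_report("a2", fx$vm, fx$bm, order_seed = seed)
  cr <- build_class_report(fx$vm, fx$bm, order_seed = seed)
  expect_identical(attr(r1, "radar")$categories,
                   attr(r2, "radar")$categories)
  expect_identical(attr(r1, "radar")$categories,
                   attr(cr, "radar")$categories)
})

test_that("radar charts render to disk and degenerate specs error", {
  fx <- report_fixture()
  rep <- build_individual_report("a1", fx$vm, fx$bm)
  p <- ggplot2::autoplot(rep)
  expect_s3_class(p, "ggplot")
  f <- tempfile(fileext = ".png")
  render_radar(rep, f, format = "png")
  expect_true(file.exists(f) && file.size(f) > 0)
  expect_error(render_radar(structure(list(), class = "not_a_spec"),
                            tempfile()),
               class = "caselogr_render_error")
})

test_that("report bundles are complete and byte-stable across reruns", {
  fx <- report_fixture()
  reps <- lapply(c("a1", "a2"), build_individual_report, fx$vm, fx$bm,
                 order_seed = 2)
  crep <- build_class_report(fx$vm, fx$bm, order_seed = 2)

  d1 <- file.path(tempfile(), "run1")
  d2 <- file.path(tempfile(), "run2")
  m1 <- write_report_bundle(reps, crep, d1, n_unmapped = 3L, order_seed = 2,
                            images = FALSE)
  m2 <- write_report_bundle(reps, crep, d2, n_unmapped = 3L, order_seed = 2,
                            images = FALSE)
  expect_setequal(list.files(d1),
                  c("resident_a1.csv", "resident_a2.csv",
                    "class_report.csv", "manifest.json"))
  for (f in setdiff(list.files(d1), "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("bytes of", f))
  }
  expect_identical(m1$config_hash, m2$config_hash)
  expect_equal(m1$n_unmapped, 3L)
})
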