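# Individual and class reports plus the radar-chart rendering that makes
# training gaps visible at a glance. All numbers serialized alongside a
# chart are the benchmark-table values themselves; the image is
# presentation only.

# run a block with a private RNG stream, leaving the caller's untouched
with_private_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Deterministic shuffled category order for radar axes
#'
#' Categories are placed in a seeded random order rather than sorted from
#' high to low, so readers scan every axis instead of fixating on the
#' extremes. The same seed gives the same order across every chart in a
#' report batch and across reruns.
#'
#' @param group_names Nonempty character vector.
#' @param order_seed Integer seed.
#' @return `group_names` permuted.
#' @export
order_categories <- function(group_names, order_seed = 0L) {
  stopifnot(length(group_names) >= 1)
  perm <- with_private_seed(order_seed, sample.int(length(group_names)))
  group_names[perm]
}

# short axis labels for crowded radar charts
radar_label <- function(group_names) {
  abbrev <- c(
    "Underweight/failure to thrive" = "Underweight/FTT",
    "Genitourinary concerns" = "GU concerns",
    "Urinary tract infection" = "UTI",
    "Overweight/obesity, increased BMI" = "Overweight/obesity",
    "Sexually transmitted infections" = "STIs",
    "Specific congenital nongenetic disorders" = "Congenital (nongenetic)",
    "Genetic and chromosomal disorders" = "Genetic/chromosomal",
    "Autism spectrum disorder" = "Autism spectrum"
  )
  out <- abbrev[group_names]
  ifelse(is.na(out), group_names, unname(out))
}

new_radar_spec <- function(categories, series, order_seed) {
  if (length(series) == 0) {
    abort("Radar spec needs at least one series", class = "caselogr_render_error")
  }
  bad <- map_lgl(series, ~ length(.x) != length(categories))
  if (any(bad)) {
    abort("Every radar series needs one value per category",
          class = "caselogr_render_error")
  }
  series <- map(series, ~ setNames(as.numeric(.x), categories))
  axis_max <- max(100, ceiling(max(unlist(series), na.rm = TRUE)))
  structure(list(categories = categories, series = series,
                 axis_max = axis_max, order_seed = order_seed),
            class = "radar_spec")
}

#' @export
print.radar_spec <- function(x, ...) {
  cat(sprintf("<radar_spec: %d categories, series: %s, axis to %g%%>\n",
              length(x$categories), paste(names(x$series), collapse = ", "),
              x$axis_max))
  invisible(x)
}

#' Build one resident's benchmark report
#'
#' Aligns the resident's unique-visit counts with their class average and
#' the graduate benchmark, adds percent-of-benchmark columns, and attaches
#' a radar spec with three series (individual, class mean, graduate =
#' 100). Individual reports are for active residents only.
#'
#' @param resident_id A single active resident.
#' @param matrix A `volume_matrix`.
#' @param benchmarks A `benchmark_table` from [build_benchmarks()].
#' @param order_seed Seed for the shared category order of the batch.
#' @return An `individual_report`: tibble with one row per group
#'   (`group`, `count`, `class_mean`, `graduate_mean`, `pct_class`,
#'   `pct_graduate`), plus attributes `resident_id`, `class_year`, `pgy`,
#'   `variety`, `as_of` and `radar` (a `radar_spec`).
#' @export
build_individual_report <- function(resident_id, matrix, benchmarks,
                                    order_seed = 0L) {
  stopifnot(inherits(matrix, "volume_matrix"),
            inherits(benchmarks, "benchmark_table"), length(resident_id) == 1)
  part <- benchmarks$partition
  if (resident_id %in% part$graduates$resident_id) {
    abort(sprintf("%s has graduated; individual reports cover active residents",
                  resident_id),
          class = "caselogr_graduated_resident")
  }
  row <- part$active[part$active$resident_id == resident_id, ]
  if (nrow(row) == 0) {
    abort(sprintf("Unknown resident: %s", resident_id),
          class = "caselogr_unknown_resident")
  }

  own <- matrix |>
    filter(.data$resident_id == .env$resident_id) |>
    select("group", "count")
  cls <- benchmarks$classes |>
    filter(.data$class_year == row$class_year) |>
    select("group", class_mean = "mean")
  tbl <- own |>
    left_join(cls, by = "group") |>
    left_join(benchmarks$graduate |> select("group", graduate_mean = "mean"),
              by = "group") |>
    mutate(
      pct_class = percent_of_benchmark(.data$count, .data$class_mean),
      pct_graduate = percent_of_benchmark(.data$count, .data$graduate_mean)
    )

  cats <- order_categories(tbl$group, order_seed)
  idx <- match(cats, tbl$group)
  radar <- new_radar_spec(
    categories = cats,
    series = list(
      individual = tbl$pct_graduate[idx],
      class = percent_of_benchmark(tbl$class_mean, tbl$graduate_mean)[idx],
      graduate = ifelse(tbl$graduate_mean[idx] > 0, 100, NA_real_)
    ),
    order_seed = order_seed
  )

  structure(tbl, class = c("individual_report", class(tbl)),
            resident_id = resident_id, class_year = row$class_year,
            pgy = row$pgy, variety = sum(tbl$count >= 1),
            as_of = benchmarks$as_of, radar = radar)
}

#' Build the class-level benchmark report
#'
#' One percent-of-graduate series per active class, for program-leadership
#' review of year-over-year exposure trends.
#'
#' @inheritParams build_individual_report
#' @return A `class_report`: tibble with one row per (class, group)
#'   (`class_year`, `pgy`, `group`, `class_mean`, `graduate_mean`,
#'   `pct_graduate`) plus attributes `as_of` and `radar`.
#' @export
build_class_report <- function(matrix, benchmarks, order_seed = 0L) {
  stopifnot(inherits(benchmarks, "benchmark_table"))
  if (nrow(benchmarks$classes) == 0) {
    abort("No active classes to report on", class = "caselogr_empty_cohort")
  }
  tbl <- benchmarks$classes |>
    rename(class_mean = "mean") |>
    left_join(benchmarks$graduate |> select("group", graduate_mean = "mean"),
              by = "group") |>
    mutate(pct_graduate = percent_of_benchmark(.data$class_mean,
                                               .data$graduate_mean))

  gnames <- benchmarks$graduate$group
  cats <- order_categories(gnames, order_seed)
  series <- tbl |>
    split(tbl$pgy) |>
    map(~ .x$pct_graduate[match(cats, .x$group)])
  series$graduate <- ifelse(
    benchmarks$graduate$mean[match(cats, gnames)] > 0, 100, NA_real_)
  radar <- new_radar_spec(cats, series, order_seed)

  structure(tbl, class = c("class_report", class(tbl)),
            as_of = benchmarks$as_of, radar = radar)
}

#' Radar (spider) chart of a report
#'
#' Each series is a closed polygon over the category axes; the 100% ring
#' (the graduate benchmark) is emphasized so shortfalls and excesses read
#' immediately. Values above 100% are drawn at true scale by default.
#' Undefined cells (zero graduate benchmark) appear as gaps, not zeros.
#'
#' @param object A `radar_spec`, `individual_report` or `class_report`.
#' @param cap_at_100 Clamp values to 100% (default `FALSE`: true scale).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot radar_spec
#' @export
autoplot.radar_spec <- function(object, cap_at_100 = FALSE, ...) {
  spec <- object
  n <- length(spec$categories)
  angle <- pi / 2 - (seq_len(n) - 1) * 2 * pi / n  # clockwise from 12 o'clock

  series_df <- imap(spec$series, function(vals, nm) {
    v <- if (cap_at_100) pmin(vals, 100) else vals
    tibble(series = nm, category = spec$categories, value = as.numeric(v),
           angle = angle)
  }) |>
    list_rbind() |>
    mutate(x = .data$value * cos(.data$angle),
           y = .data$value * sin(.data$angle))
  # close each polygon; NA cells break the path into gaps
  closed <- series_df |>
    group_by(.data$series) |>
    group_modify(~ bind_rows(.x, .x[1, ])) |>
    ungroup()

  axis_max <- if (cap_at_100) 100 else spec$axis_max
  rings <- seq(25, axis_max, by = 25)
  ring_df <- tidyr::crossing(ring = rings, i = seq_len(n + 1)) |>
    mutate(a = pi / 2 - (.data$i - 1) * 2 * pi / n,
           x = .data$ring * cos(.data$a), y = .data$ring * sin(.data$a))
  spoke_df <- tibble(angle = angle, x = axis_max * cos(angle),
                     y = axis_max * sin(angle))
  label_df <- tibble(
    label = radar_label(spec$categories),
    x = 1.12 * axis_max * cos(angle), y = 1.12 * axis_max * sin(angle),
    hjust = ifelse(cos(angle) > 0.2, 0, ifelse(cos(angle) < -0.2, 1, 0.5))
  )

  ggplot2::ggplot() +
    ggplot2::geom_path(
      data = ring_df |> filter(.data$ring != 100),
      ggplot2::aes(.data$x, .data$y, group = .data$ring),
      colour = "grey85", linewidth = 0.3) +
    ggplot2::geom_path(
      data = ring_df |> filter(.data$ring == 100),
      ggplot2::aes(.data$x, .data$y, group = .data$ring),
      colour = "grey40", linewidth = 0.6) +
    ggplot2::geom_segment(
      data = spoke_df,
      ggplot2::aes(x = 0, y = 0, xend = .data$x, yend = .data$y),
      colour = "grey90", linewidth = 0.3) +
    ggplot2::geom_path(
      data = closed,
      ggplot2::aes(.data$x, .data$y, colour = .data$series),
      linewidth = 0.8, na.rm = TRUE) +
    ggplot2::geom_point(
      data = series_df,
      ggplot2::aes(.data$x, .data$y, colour = .data$series),
      size = 1.2, na.rm = TRUE) +
    ggplot2::geom_text(
      data = label_df,
      ggplot2::aes(.data$x, .data$y, label = .data$label, hjust = .data$hjust),
      size = 2.6) +
    ggplot2::coord_equal(xlim = c(-1.45, 1.45) * axis_max,
                         ylim = c(-1.3, 1.3) * axis_max) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL,
                  caption = "Axes in % of graduate benchmark; heavy ring = 100%") +
    ggplot2::theme(legend.position = "bottom")
}

#' @rdname autoplot.radar_spec
#' @method autoplot individual_report
#' @export
autoplot.individual_report <- function(object, ...) {
  p <- autoplot.radar_spec(attr(object, "radar"), ...)
  p + ggplot2::labs(
    title = sprintf("Resident %s (%s) vs class and graduate benchmarks",
                    attr(object, "resident_id"), attr(object, "pgy")),
    subtitle = sprintf("as of %s; variety %d/%d groups",
                       attr(object, "as_of"), attr(object, "variety"),
                       nrow(object)))
}

#' @rdname autoplot.radar_spec
#' @method autoplot class_report
#' @export
autoplot.class_report <- function(object, ...) {
  p <- autoplot.radar_spec(attr(object, "radar"), ...)
  p + ggplot2::labs(title = "Class averages vs graduate benchmark",
                    subtitle = sprintf("as of %s", attr(object, "as_of")))
}

#' Render a radar chart to disk
#'
#' @param spec A `radar_spec` (or a report carrying one).
#' @param path Output path.
#' @param format `"png"` or `"svg"`.
#' @param ... Passed to [autoplot.radar_spec()].
#' @return `path`, invisibly.
#' @export
render_radar <- function(spec, path, format = c("png", "svg"), ...) {
  format <- match.arg(format)
  if (!inherits(spec, "radar_spec")) spec <- attr(spec, "radar")
  if (is.null(spec)) {
    abort("No radar spec to render", class = "caselogr_render_error")
  }
  p <- autoplot.radar_spec(spec, ...)
  tryCatch({
    ggplot2::ggsave(path, p, device = format, width = 7, height = 6.5,
                    dpi = 150)
    TRUE
  }, error = function(e) {
    abort(sprintf("Failed to render %s: %s", path, conditionMessage(e)),
          class = "caselogr_render_error")
  })
  invisible(path)
}

#' Write a full report bundle
#'
#' Emits, under `out_dir`: one CSV (and optionally one radar image) per
#' individual report, the class report CSV/image, and `manifest.json`
#' recording the as-of date, seed, config hash, unmapped-code tally and
#' file list. Reruns with identical inputs and seed produce byte-identical
#' CSVs.
#'
#' @param individual_reports List of `individual_report`s.
#' @param class_report A `class_report`.
#' @param out_dir Output directory (created if absent).
#' @param n_unmapped Unmapped-code tally from the volume matrix.
#' @param order_seed The batch's category-order seed.
#' @param images Render radar images too (default `TRUE`; CSVs alone are
#'   faster for tests).
#' @param format Image format.
#' @return Invisibly, the manifest as a list.
#' @export
write_report_bundle <- function(individual_reports, class_report, out_dir,
                                n_unmapped = 0L, order_seed = 0L,
                                images = TRUE, format = "png") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0) {
    abort(sprintf("Output directory not writable: %s", out_dir),
          class = "caselogr_io_error")
  }
  files <- character()
  for (rep in individual_reports) {
    rid <- attr(rep, "resident_id")
    csv <- file.path(out_dir, sprintf("resident_%s.csv", rid))
    readr::write_csv(as_tibble(rep), csv, progress = FALSE)
    files <- c(files, csv)
    if (images) {
      img <- file.path(out_dir, sprintf("resident_%s.%s", rid, format))
      render_radar(rep, img, format = format)
      files <- c(files, img)
    }
  }
  cls_csv <- file.path(out_dir, "class_report.csv")
  readr::write_csv(as_tibble(class_report), cls_csv, progress = FALSE)
  files <- c(files, cls_csv)
  if (images) {
    img <- file.path(out_dir, paste0("class_report.", format))
    render_radar(class_report, img, format = format)
    files <- c(files, img)
  }

  manifest <- list(
    as_of = format(attr(class_report, "as_of")),
    order_seed = order_seed,
    n_unmapped = n_unmapped,
    config_hash = rlang::hash(list(
      map(individual_reports, as_tibble), as_tibble(class_report))),
    files = basename(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
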