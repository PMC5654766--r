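# End-to-end orchestration: simulate (or ingest) -> clean -> trips ->
# labels -> ARS -> associations -> statistics, deterministic under a seed.

#' Default pipeline configuration
#'
#' Collects every stage threshold with its field default: 90 km/h speed cap,
#' 120-s analysis grid, 500-m colony radius for trip splitting, printed
#' behaviour delimiters, ARS run/merge rule (3 fixes / gap of 3), the
#' 0.002-degree / 30-s association rule with 50-m nest exclusion, 60-s
#' group-size bins, and the three 12-day monitoring periods.
#'
#' @param separable Passed to [default_sim_config()] for simulated runs.
#' @param seed Seed for the simulated colony.
#' @return A `run_config` list.
#' @export
default_run_config <- function(separable = TRUE, seed = 42) {
  cfg <- list(
    sim = default_sim_config(separable = separable, seed = seed),
    colony = colony_site(),
    colony_radius_m = 500,
    step_s = 120,
    vmax_kmh = 90,
    delimiters = default_delimiters(),
    min_run = 3,
    max_gap = 3,
    dlat = 0.002,
    dlon = 0.002,
    dt_s = 30,
    nest_radius_m = 50,
    bin_s = 60,
    duration_bounds_h = c(0, 24),
    utc_offset_h = 3,
    periods = paper_periods(),
    ud_isopleths = c(50, 95),
    ud_min_points = 5
  )
  class(cfg) <- "run_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Scalar thresholds found in the file override the defaults from
#' [default_run_config()]; everything else keeps its default.
#'
#' @param path YAML file of `key: value` thresholds.
#' @param base Configuration to override.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, base = default_run_config()) {
  vals <- yaml::read_yaml(path)
  known <- intersect(names(vals), names(base))
  unknown <- setdiff(names(vals), names(base))
  if (length(unknown)) {
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (k in known) base[[k]] <- vals[[k]]
  base
}

#' Run the full analysis pipeline
#'
#' Either simulates a colony from `config$sim` or analyses a supplied fix
#' table. Stages: per-bird speed filter on the raw fixes; interpolation onto
#' the analysis grid; trip splitting and outlier flagging; behaviour
#' labelling; behaviour budgets; ARS table and kernel utilisation areas;
#' trip summaries grouped by period and age; association detection on the
#' raw (non-interpolated) cleaned fixes with nest filtering and single-event
#' pruning; group sizes; and the ARS x association independence test, with
#' the ARS fraction recomputed from the pipeline's own labels.
#'
#' @param config A `run_config`.
#' @param fixes Optional fix tibble; when NULL a colony is simulated.
#' @return A report bundle (list); see the elements returned below. Includes
#'   `log`, a per-stage record of counts in/out.
#' @export
run_pipeline <- function(config = default_run_config(), fixes = NULL) {
  truth <- NULL
  if (is.null(fixes)) {
    sim <- simulate_colony(config$sim)
    fixes <- sim$fixes
    truth <- sim$truth
  }
  log <- list(fixes_in = nrow(fixes))
  if (nrow(fixes) == 0) {
    return(empty_bundle(config, log))
  }
  tracks <- split(fixes, fixes$bird_id)

  clean <- lapply(tracks, filter_speed, vmax_kmh = config$vmax_kmh)
  raw_clean <- dplyr::bind_rows(clean)
  log$fixes_removed_speed <- log$fixes_in - nrow(raw_clean)
  log$fixes_retained <- nrow(raw_clean)

  interp <- dplyr::bind_rows(lapply(clean[vapply(clean, nrow, 0L) >= 2],
                                    interpolate_track, step_s = config$step_s))
  trips <- dplyr::bind_rows(lapply(split(interp, interp$bird_id), split_trips,
                                   colony = config$colony,
                                   colony_radius_m = config$colony_radius_m))
  trip_flags <- flag_outlier_trips(trips, config$duration_bounds_h)
  log$n_trips <- nrow(trip_flags)
  log$n_trips_excluded <- sum(trip_flags$excluded)

  keep_ids <- trip_flags$trip_id[!trip_flags$excluded]
  kept <- trips[trips$trip_id %in% keep_ids, ]
  labellable <- names(which(table(kept$trip_id) >= 3))
  labelled <- dplyr::bind_rows(lapply(
    split(kept[kept$trip_id %in% labellable, ],
          kept$trip_id[kept$trip_id %in% labellable]),
    label_trip, delimiters = config$delimiters))

  budgets <- if (nrow(labelled) && any(!is.na(labelled$behaviour))) {
    behaviour_budget(labelled, by = "age_class")
  } else NULL

  ars <- if (nrow(labelled)) {
    ars_table(labelled, config$colony, config$min_run, config$max_gap)
  } else ars_table(labelled[0, ], config$colony)

  in_ars <- rep(FALSE, nrow(labelled))
  if (nrow(ars) && nrow(labelled)) {
    for (i in seq_len(nrow(ars))) {
      in_ars <- in_ars | (labelled$bird_id == ars$bird_id[i] &
                            labelled$t >= ars$start[i] &
                            labelled$t <= ars$end[i])
    }
  }
  lab_ok <- !is.na(labelled$behaviour)
  f_ars <- if (any(lab_ok)) mean(in_ars[lab_ok]) else NA_real_

  ud <- NULL
  ars_fix <- labelled[in_ars, ]
  if (nrow(ars_fix) >= config$ud_min_points) {
    ud <- kernel_ud(ars_fix$lat, ars_fix$lon,
                    isopleths = config$ud_isopleths)
  }

  summaries <- summarise_trips(trips[trips$trip_id %in% keep_ids, ],
                               config$colony, config$colony_radius_m,
                               config$utc_offset_h, periods = config$periods)
  groups <- if (nrow(summaries)) group_summaries(summaries) else NULL

  events <- detect_all_pairs(raw_clean, config$dlat, config$dlon, config$dt_s)
  log$events_detected <- nrow(events)
  events <- filter_nest(events, config$colony, config$nest_radius_m)
  log$events_at_sea <- nrow(events)
  events <- prune_single(events)
  log$events_pruned <- nrow(events)
  groups_sizes <- group_sizes(events, config$bin_s)

  assoc_stats <- NULL
  if (nrow(events) && !is.na(f_ars) && f_ars > 0 && f_ars < 1) {
    in_zone <- function(bird, t) {
      out <- rep(FALSE, length(bird))
      for (i in seq_len(nrow(ars))) {
        out <- out | (bird == ars$bird_id[i] &
                        t >= ars$start[i] & t <= ars$end[i])
      }
      out
    }
    k <- in_zone(events$bird_a, events$t_a) +
      in_zone(events$bird_b, events$t_b)
    observed <- c(sum(k == 0), sum(k == 1), sum(k == 2))
    assoc_stats <- tryCatch(
      c(list(f_ars = f_ars), ars_association_test(observed, f_ars)),
      warning = function(w) {
        suppressWarnings(c(list(f_ars = f_ars),
                           ars_association_test(observed, f_ars)))
      })
  }

  list(config = config, fixes = fixes, truth = truth, raw_clean = raw_clean,
       trips = trips, trip_flags = trip_flags, labelled = labelled,
       budgets = budgets, ars = ars, f_ars = f_ars, ud = ud,
       summaries = summaries, groups = groups, events = events,
       group_sizes = groups_sizes, stats = assoc_stats, log = log)
}

empty_bundle <- function(config, log) {
  list(config = config, fixes = empty_fixes(), truth = NULL,
       raw_clean = empty_fixes(),
       trips = NULL, trip_flags = flag_outlier_trips(
         dplyr::mutate(empty_fixes(), trip_id = character(),
                       complete = logical())),
       labelled = NULL, budgets = NULL,
       ars = ars_table(dplyr::mutate(empty_fixes(), trip_id = character(),
                                     behaviour = character(),
                                     v_kmh = numeric(),
                                     theta_rad = numeric()),
                       config$colony),
       f_ars = NA_real_, ud = NULL, summaries = NULL, groups = NULL,
       events = empty_events(),
       group_sizes = group_sizes(empty_events()), stats = NULL, log = log)
}

#' Write a report bundle to disk
#'
#' CSV tables for trips, budgets, ARS zones, trip summaries and events, plus
#' a JSON statistics report
#' (`{f_ars, expected: [p0, p1, p2], observed, chi2, df, p}`).
#'
#' @param bundle Output of [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  wr <- function(x, name) {
    if (is.null(x)) return()
    p <- file.path(dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    written <<- c(written, p)
  }
  wr(bundle$trip_flags, "trips.csv")
  wr(bundle$budgets, "behaviour_budget.csv")
  wr(bundle$ars, "ars_zones.csv")
  wr(bundle$summaries, "trip_summaries.csv")
  wr(bundle$groups, "trip_group_summaries.csv")
  wr(bundle$events, "association_events.csv")
  wr(bundle$group_sizes, "group_sizes.csv")
  stats_path <- file.path(dir, "stats.json")
  s <- bundle$stats
  payload <- if (is.null(s)) {
    list(f_ars = bundle$f_ars, note = "no association events")
  } else {
    list(f_ars = s$f_ars, expected = unname(s$expected),
         observed = unname(s$observed), chi2 = s$statistic, df = s$df,
         p = s$p_value)
  }
  jsonlite::write_json(payload, stats_path, auto_unbox = TRUE, digits = NA)
  written <- c(written, stats_path)
  invisible(written)
}

#' Figures for a report bundle
#'
#' Writes up to four deterministic files into `dir`: group-size bar chart,
#' trip-metric box plots, stacked behaviour budgets, and (when ARS zones
#' exist) an ARS range histogram; the ARS figure is skipped with a warning
#' on an empty ARS table.
#'
#' @param bundle Output of [run_pipeline()].
#' @param dir Output directory.
#' @return Character vector of files written, invisibly.
#' @export
make_figures <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  save_plot <- function(p, name) {
    path <- file.path(dir, name)
    ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 150)
    written <<- c(written, path)
  }

  gs <- bundle$group_sizes
  gtab <- if (!is.null(gs) && nrow(gs)) {
    dplyr::count(gs, group = .data$n_partners + 1L)
  } else {
    tibble::tibble(group = 1L, n = 0L)
  }
  save_plot(
    ggplot2::ggplot(gtab, ggplot2::aes(x = factor(.data$group), y = .data$n)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "birds in group", y = "bird-minutes",
                    title = "At-sea group sizes"),
    "fig_group_sizes.png")

  sm <- bundle$summaries
  if (!is.null(sm) && nrow(sm)) {
    long <- tidyr::pivot_longer(sm, c("duration_h", "total_distance_km",
                                      "max_range_km"),
                                names_to = "metric", values_to = "value")
    save_plot(
      ggplot2::ggplot(long, ggplot2::aes(x = .data$age_class,
                                         y = .data$value)) +
        ggplot2::geom_boxplot() +
        ggplot2::facet_wrap(~metric, scales = "free_y") +
        ggplot2::labs(x = NULL, y = NULL, title = "Trip metrics"),
      "fig_trip_metrics.png")
  } else {
    save_plot(ggplot2::ggplot() + ggplot2::theme_void() +
                ggplot2::labs(title = "No trips"), "fig_trip_metrics.png")
  }

  bg <- bundle$budgets
  if (!is.null(bg) && nrow(bg)) {
    save_plot(
      ggplot2::ggplot(bg, ggplot2::aes(x = .data$age_class, y = .data$mean,
                                       fill = .data$behaviour)) +
        ggplot2::geom_col(position = "stack") +
        ggplot2::labs(x = NULL, y = "mean proportion",
                      title = "Behaviour budget"),
      "fig_behaviour_budget.png")
  } else {
    save_plot(ggplot2::ggplot() + ggplot2::theme_void() +
                ggplot2::labs(title = "No labelled fixes"),
              "fig_behaviour_budget.png")
  }

  if (!is.null(bundle$ars) && nrow(bundle$ars)) {
    save_plot(
      ggplot2::ggplot(bundle$ars, ggplot2::aes(x = .data$range_km)) +
        ggplot2::geom_histogram(bins = 20) +
        ggplot2::labs(x = "ARS range from colony (km)", y = "zones",
                      title = "ARS zones"),
      "fig_ars_zones.png")
  } else {
    warning("empty ARS table: ARS figure skipped", call. = FALSE)
  }
  invisible(written)
}
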