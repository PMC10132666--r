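#' Pipeline configuration
#'
#' Assembles the full configuration of the monitoring pipeline with the
#' study's defaults: 500 m / min_pts 1 place clustering scoped per user-day,
#' Monday-start weeks, Europe/London civil days, mean + 1 SD abnormal-account
#' cleaning, the three epidemic analysis windows with their pre-epidemic
#' baseline windows, arrival-share attractiveness, k = 3 profile clustering
#' and permutation inference settings.
#'
#' @param outdir output directory for stage artifacts.
#' @param points,zones,cases optional input paths (points CSV/JSON-lines,
#'   zones GeoJSON, cases CSV); unnecessary when the `simulate` stage
#'   generates them.
#' @param overrides named list merged over the defaults (nested lists merge
#'   recursively), e.g. `list(clustering = list(radius_m = 300))`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = "mobflow_out", points = NULL,
                            zones = NULL, cases = NULL, overrides = list()) {
  cfg <- list(
    paths = list(points = points, zones = zones, cases = cases,
                 outdir = outdir),
    clustering = list(radius_m = 500, min_pts = 1, scope = "user-day"),
    timezone = "Europe/London",
    cleaning = list(k_sd = 1),
    periods = list(
      first_wave = c("2020-03-02", "2020-06-28"),
      summer = c("2020-06-29", "2020-11-01"),
      second_wave = c("2020-11-02", "2021-02-28")
    ),
    baselines = list(
      first_wave = c("2019-03-04", "2019-06-30"),
      summer = c("2019-07-01", "2019-11-03"),
      second_wave = c("2019-11-04", "2020-03-01")
    ),
    attractiveness = list(direction = "in"),
    profiles = list(k = 3, linkage = "average"),
    spatial = list(n_perm = 199, alpha = 0.05),
    simulate = list(rows = 8, cols = 8, cell_deg = 0.02,
                    origin = c(51.3, -0.5), scenario = list(),
                    cases = list()),
    seed = 1L
  )
  cfg <- utils::modifyList(cfg, overrides)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values in the file override the defaults of [pipeline_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(overrides = yaml::read_yaml(path))
}

stage_path <- function(cfg, file) file.path(cfg$paths$outdir, file)

need_file <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop_mobflow("missing prerequisite output ", path,
                 "; run the `", produced_by, "` stage first")
  }
  path
}

#' Run the monitoring pipeline
#'
#' Orchestrates the pipeline stages: `simulate` (synthetic zones, activity
#' stream, ground truth and case surface), `clean`, `trips`, `indices`,
#' `network`, `profiles`, `spatial`, and `all` (every stage in order). Each
#' stage reads its inputs from the configured paths or from the previous
#' stage's files under `outdir`, writes plain-text outputs (CSV/GeoJSON/
#' JSON), and a run manifest (`manifest.json`: config, seed, file checksums
#' and row counts) is refreshed after every run.
#'
#' @param stage one of `"simulate"`, `"clean"`, `"trips"`, `"indices"`,
#'   `"network"`, `"profiles"`, `"spatial"`, `"all"`.
#' @param config a [pipeline_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return the configuration, invisibly; outputs land under
#'   `config$paths$outdir`.
#' @export
run_pipeline <- function(stage = "all", config = pipeline_config(),
                         seed = NULL) {
  stages <- c("simulate", "clean", "trips", "indices", "network",
              "profiles", "spatial")
  stage <- match.arg(stage, c(stages, "all"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(config$paths$outdir, showWarnings = FALSE, recursive = TRUE)
  todo <- if (stage == "all") stages else stage
  for (s in todo) {
    message("[mobflow] stage: ", s)
    switch(s,
      simulate = stage_simulate(config),
      clean = stage_clean(config),
      trips = stage_trips(config),
      indices = stage_indices(config),
      network = stage_network(config),
      profiles = stage_profiles(config),
      spatial = stage_spatial(config)
    )
  }
  write_manifest(config)
  invisible(config)
}

load_zones_cfg <- function(cfg) {
  path <- cfg$paths$zones %||% stage_path(cfg, "zones.geojson")
  read_zones_geojson(need_file(path, "simulate"))
}

stage_simulate <- function(cfg) {
  sim <- cfg$simulate
  zones <- generate_zones(sim$rows, sim$cols, sim$cell_deg,
                          origin = unlist(sim$origin))
  sc_args <- utils::modifyList(list(seed = cfg$seed), sim$scenario)
  scenario <- do.call(activity_scenario, sc_args)
  stream <- generate_activity_stream(zones, scenario,
                                     radius_m = cfg$clustering$radius_m)
  write_zones_geojson(zones, stage_path(cfg, "zones.geojson"))
  write_points(stream$points, stage_path(cfg, "points.csv"))
  utils::write.csv(stream$truth_trips, stage_path(cfg, "truth_trips.csv"),
                   row.names = FALSE)
  utils::write.csv(stream$truth_movers, stage_path(cfg, "truth_movers.csv"),
                   row.names = FALSE)
  # planted case surface, coupled to the true weekly arrival shares
  tt <- stream$truth_trips
  if (nrow(tt)) {
    tt$dest_zone <- locate_zones(tt$dest_lat, tt$dest_lon, zones)
    tt <- tt[!is.na(tt$dest_zone), ]
    wk <- week_start(tt$date)
    arr <- data.table::data.table(week_start = wk, zone_id = tt$dest_zone)
    n <- NULL
    arr <- arr[, list(n = .N), by = c("week_start", "zone_id")]
    tot <- tapply(arr$n, arr$week_start, sum)
    attr_true <- tibble::tibble(
      week_start = arr$week_start, zone_id = arr$zone_id,
      share = arr$n / as.numeric(tot[as.character(arr$week_start)])
    )
    cs_args <- utils::modifyList(list(seed = cfg$seed + 1L), sim$cases)
    cscn <- do.call(case_scenario, cs_args)
    cases <- generate_cases(zones, queen_weights(zones), attr_true, cscn)
    write_cases_csv(cases, stage_path(cfg, "cases.csv"))
  }
  invisible(NULL)
}

stage_clean <- function(cfg) {
  pts_path <- cfg$paths$points %||% stage_path(cfg, "points.csv")
  pts <- read_points(need_file(pts_path, "simulate"),
                     format = if (grepl("jsonl$", pts_path)) "jsonl" else "csv")
  zones <- load_zones_cfg(cfg)
  res <- clean_points(pts, zones, k_sd = cfg$cleaning$k_sd)
  write_points(res$points, stage_path(cfg, "points_clean.csv"))
  write_cleaning_report(res$report, stage_path(cfg, "cleaning_report.json"))
  invisible(NULL)
}

stage_trips <- function(cfg) {
  pts <- read_points(need_file(stage_path(cfg, "points_clean.csv"), "clean"))
  zones <- load_zones_cfg(cfg)
  trips <- extract_daily_trips(pts, radius_m = cfg$clustering$radius_m,
                               min_pts = cfg$clustering$min_pts,
                               tz = cfg$timezone,
                               scope = cfg$clustering$scope)
  trips <- assign_zones(trips, zones)
  utils::write.csv(trips, stage_path(cfg, "trips.csv"), row.names = FALSE)
  invisible(NULL)
}

read_trips_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(user_id = "character",
                                             date = "Date"))
  tibble::as_tibble(df)
}

stage_indices <- function(cfg) {
  trips <- read_trips_csv(need_file(stage_path(cfg, "trips.csv"), "trips"))
  pts <- read_points(need_file(stage_path(cfg, "points_clean.csv"), "clean"))
  ix <- daily_indices(trips, pts, tz = cfg$timezone)
  utils::write.csv(ix, stage_path(cfg, "daily_indices.csv"), row.names = FALSE)
  utils::write.csv(summarize_indices(ix), stage_path(cfg, "index_summary.csv"),
                   row.names = FALSE)
  if (nrow(ix) >= 14) {
    dec <- decompose_series(ix$m_rate, period = 7, dates = ix$date)
    utils::write.csv(dec, stage_path(cfg, "m_rate_decomposition.csv"),
                     row.names = FALSE)
  }
  invisible(NULL)
}

stage_network <- function(cfg) {
  trips <- read_trips_csv(need_file(stage_path(cfg, "trips.csv"), "trips"))
  od <- build_weekly_od(trips)
  utils::write.csv(od, stage_path(cfg, "weekly_od.csv"), row.names = FALSE)
  attr_wk <- attractiveness_series(od, direction = cfg$attractiveness$direction)
  utils::write.csv(attr_wk, stage_path(cfg, "weekly_attractiveness.csv"),
                   row.names = FALSE)
  sums <- dplyr::bind_rows(lapply(sort(unique(od$week_start)), function(w) {
    tibble::add_column(network_summary(flow_network(od[od$week_start == w, ])),
                       week_start = w, .before = 1)
  }))
  utils::write.csv(sums, stage_path(cfg, "network_summaries.csv"),
                   row.names = FALSE)
  pods <- aggregate_periods(od, cfg$periods)
  bods <- aggregate_periods(od, cfg$baselines)
  rows <- list(); comm <- list()
  for (nm in names(cfg$periods)) {
    pe <- pods[pods$period == nm, ]
    if (!nrow(pe)) next
    net <- flow_network(pe, period = nm)
    a_curr <- attractiveness(net, cfg$attractiveness$direction)
    be <- bods[bods$period == nm, ]
    if (nrow(be)) {
      a_base <- attractiveness(flow_network(be, period = nm),
                               cfg$attractiveness$direction)
      d <- attractiveness_diff(a_curr, a_base)
      rows[[nm]] <- tibble::add_column(d, period = nm, .before = 1)
    }
    cp <- detect_communities(net)
    comm[[nm]] <- tibble::add_column(cp$membership, period = nm,
                                     modularity = cp$modularity, .before = 1)
  }
  if (length(rows)) {
    utils::write.csv(dplyr::bind_rows(rows),
                     stage_path(cfg, "attractiveness_diff.csv"),
                     row.names = FALSE)
  }
  if (length(comm)) {
    utils::write.csv(dplyr::bind_rows(comm),
                     stage_path(cfg, "communities.csv"), row.names = FALSE)
  }
  invisible(NULL)
}

stage_profiles <- function(cfg) {
  attr_wk <- utils::read.csv(
    need_file(stage_path(cfg, "weekly_attractiveness.csv"), "network"),
    colClasses = c(week_start = "Date", zone_id = "character")
  )
  weeks <- week_index(min(attr_wk$week_start), max(attr_wk$week_start))
  prof <- build_profiles(attr_wk, weeks)
  utils::write.csv(data.frame(zone_id = rownames(prof), prof,
                              check.names = FALSE),
                   stage_path(cfg, "profiles.csv"), row.names = FALSE)
  usable <- sum(apply(prof, 1, stats::var) > 0)
  if (usable >= cfg$profiles$k && ncol(prof) >= 3) {
    cl <- cluster_profiles(prof, k = cfg$profiles$k,
                           linkage = cfg$profiles$linkage)
    utils::write.csv(cl$labels, stage_path(cfg, "profile_clusters.csv"),
                     row.names = FALSE)
  } else {
    message("too few usable profiles for clustering; skipped")
  }
  invisible(NULL)
}

stage_spatial <- function(cfg) {
  zones <- load_zones_cfg(cfg)
  cases_path <- cfg$paths$cases %||% stage_path(cfg, "cases.csv")
  cases <- read_cases_csv(need_file(cases_path, "simulate"))
  attr_wk <- utils::read.csv(
    need_file(stage_path(cfg, "weekly_attractiveness.csv"), "network"),
    colClasses = c(week_start = "Date", zone_id = "character")
  )
  w <- queen_weights(zones)
  suite <- weekly_correlation_suite(attr_wk, cases, w,
                                    n_perm = cfg$spatial$n_perm,
                                    seed = cfg$seed,
                                    alpha = cfg$spatial$alpha)
  utils::write.csv(suite, stage_path(cfg, "weekly_correlations.csv"),
                   row.names = FALSE)
  diff_path <- stage_path(cfg, "attractiveness_diff.csv")
  if (file.exists(diff_path)) {
    diffs <- utils::read.csv(diff_path, colClasses = c(zone_id = "character"))
    psuite <- period_correlation_suite(diffs, cases, w, cfg$periods,
                                       n_perm = cfg$spatial$n_perm,
                                       seed = cfg$seed + 1000L,
                                       alpha = cfg$spatial$alpha)
    utils::write.csv(psuite, stage_path(cfg, "period_correlations.csv"),
                     row.names = FALSE)
  }
  invisible(NULL)
}

write_manifest <- function(cfg) {
  files <- list.files(cfg$paths$outdir, full.names = TRUE)
  files <- files[!grepl("manifest.json$", files)]
  info <- lapply(files, function(f) {
    list(file = basename(f),
         md5 = unname(tools::md5sum(f)),
         bytes = file.info(f)$size)
  })
  jsonlite::write_json(
    list(seed = cfg$seed, config = unclass(cfg), outputs = info,
         generated_by = paste0("mobflow ",
                               as.character(utils::packageVersion("mobflow")))),
    stage_path(cfg, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(NULL)
}
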