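#' Activity-stream scenario
#'
#' Bundles the parameters of the synthetic geo-located activity generator.
#' The defaults emulate the empirical features of a city-scale geotagged
#' social-media stream during an epidemic monitoring study: a modest daily
#' moving-user fraction, log-normal trip distances with a median near 5.4 km,
#' coordinate jitter well below the 500 m place-clustering radius, and a
#' double-peaked diurnal posting profile.
#'
#' @param n_users number of users.
#' @param n_days number of consecutive days.
#' @param start_date first civil day (Date or string).
#' @param p_mover probability a user makes at least one trip on a given day.
#'   Either a single value or a vector of length `n_days` (e.g. a step change
#'   emulating a lockdown shock).
#' @param trips_lambda Poisson rate of extra trips on a mover day (trip count
#'   is `1 + Poisson(trips_lambda)`).
#' @param dist_median_m,dist_sdlog log-normal trip-distance parameters:
#'   median in meters and log-scale dispersion.
#' @param jitter_m maximum coordinate noise around a visited place, meters;
#'   must stay below the place-clustering radius.
#' @param points_lambda Poisson rate of extra points per place visit (count
#'   is `1 + Poisson(points_lambda)`).
#' @param diurnal_weights 24 non-negative hourly posting weights; the default
#'   is double-peaked (morning and evening).
#' @param place_intensity `"centre"` (activity concentrated toward the study
#'   area's centre) or `"uniform"`.
#' @param tz timezone in which civil days and the diurnal profile are
#'   defined.
#' @param seed integer seed; the generator is fully reproducible.
#' @return an `activity_scenario` list.
#' @export
activity_scenario <- function(n_users = 2000, n_days = 30,
                              start_date = "2019-01-07",
                              p_mover = 0.3, trips_lambda = 0.3,
                              dist_median_m = 5400, dist_sdlog = 0.8,
                              jitter_m = 50, points_lambda = 0.5,
                              diurnal_weights = default_diurnal_weights(),
                              place_intensity = c("centre", "uniform"),
                              tz = "Europe/London", seed = 1L) {
  place_intensity <- match.arg(place_intensity)
  if (any(p_mover < 0) || any(p_mover > 1)) stop_mobflow("p_mover must be in [0, 1]")
  if (!(length(p_mover) %in% c(1L, n_days))) {
    stop_mobflow("p_mover must have length 1 or n_days")
  }
  if (length(diurnal_weights) != 24 || any(diurnal_weights < 0) ||
      sum(diurnal_weights) <= 0) {
    stop_mobflow("diurnal_weights must be 24 non-negative values with positive sum")
  }
  structure(
    list(
      n_users = as.integer(n_users), n_days = as.integer(n_days),
      start_date = as.Date(start_date),
      p_mover = p_mover, trips_lambda = trips_lambda,
      dist_median_m = dist_median_m, dist_sdlog = dist_sdlog,
      jitter_m = jitter_m, points_lambda = points_lambda,
      diurnal_weights = diurnal_weights, place_intensity = place_intensity,
      tz = tz, seed = as.integer(seed)
    ),
    class = "activity_scenario"
  )
}

#' Default double-peaked diurnal posting profile
#'
#' Hourly weights with a morning peak around 08:00-09:00 and a larger
#' evening peak around 19:00, plus a small night-time floor.
#'
#' @return numeric vector of 24 weights.
#' @export
default_diurnal_weights <- function() {
  h <- 0:23
  stats::dnorm(h, mean = 8.5, sd = 2) + 1.4 * stats::dnorm(h, mean = 19, sd = 2.5) + 0.02
}

# spherical destination point, R = 6371000 m; vectorized
dest_point <- function(lat, lon, bearing_deg, dist_m) {
  R <- 6371000
  phi1 <- lat * pi / 180
  lam1 <- lon * pi / 180
  th <- bearing_deg * pi / 180
  delta <- dist_m / R
  phi2 <- asin(sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(th))
  lam2 <- lam1 + atan2(
    sin(th) * sin(delta) * cos(phi1),
    cos(delta) - sin(phi1) * sin(phi2)
  )
  cbind(lat = phi2 * 180 / pi, lon = lam2 * 180 / pi)
}

in_bbox <- function(lat, lon, bbox) {
  lon >= bbox[1] & lat >= bbox[2] & lon <= bbox[3] & lat <= bbox[4]
}

# local civil clock time -> POSIXct instant (not midnight + offset, which
# would drift across the DST change). Clock times falling into the
# spring-forward gap have no instant; parsers resolve them inconsistently
# (NA or a pre-gap instant, which would break chronological order), so they
# are detected by a round-trip check and pushed one hour later, staying
# inside the same civil day.
civil_time <- function(date, secs, tz) {
  h <- floor(secs / 3600)
  m <- floor((secs - h * 3600) / 60)
  s <- secs - h * 3600 - m * 60
  t <- as.POSIXct(sprintf("%s %02d:%02d:%06.3f", format(date), h, m, s),
                  tz = tz, format = "%Y-%m-%d %H:%M:%OS")
  roundtrip <- format(t, "%H", tz = tz)
  gap <- is.na(t) | is.na(roundtrip) | roundtrip != sprintf("%02d", h)
  if (any(gap)) {
    shifted <- as.POSIXct(
      sprintf("%s %02d:%02d:%06.3f", format(date), h + 1, m, s),
      tz = tz, format = "%Y-%m-%d %H:%M:%OS"
    )
    t[gap] <- shifted[gap]
  }
  t
}

#' Generate a synthetic geo-located activity stream with ground truth
#'
#' Simulates users posting geo-located points inside a zone system. Each user
#' has a home activity place (zone chosen by the scenario's spatial
#' intensity). On a mover day the user performs a chain of trips whose
#' distances are log-normal draws constrained to exceed the place-clustering
#' radius, so downstream place detection can recover the planted trips
#' exactly; every visited place emits one or more points jittered by at most
#' `jitter_m`. Timestamps follow the scenario's diurnal profile and are
#' assigned in visit order, so the chronological point sequence traces the
#' trip chain.
#'
#' @param zones a [zone_system()].
#' @param scenario an [activity_scenario()].
#' @param radius_m the place-clustering radius the stream is designed
#'   against (default 500); `jitter_m` must be smaller and planted trip
#'   distances always exceed it.
#' @return a list with `points` (point tibble: `user_id`, `timestamp` (UTC),
#'   `lat`, `lon`), `truth_trips` (planted trips: `user_id`, `date`,
#'   `trip_index`, origin/dest coordinates, `distance_m`) and `truth_movers`
#'   (`user_id`, `date`, `mover` flag for every user-day).
#' @export
generate_activity_stream <- function(zones, scenario, radius_m = 500) {
  stopifnot(inherits(scenario, "activity_scenario"))
  if (scenario$jitter_m >= radius_m) {
    stop_mobflow("jitter_m must be smaller than the clustering radius ",
                 "(jitter at or above the radius corrupts place recovery)")
  }
  set.seed(scenario$seed)
  bbox <- zones$bbox
  n_users <- scenario$n_users
  n_days <- scenario$n_days
  dates <- scenario$start_date + seq_len(n_days) - 1L
  p_mover <- rep(scenario$p_mover, length.out = n_days)

  # home places: zone by spatial intensity, position uniform in the zone
  cent <- zone_centroids(zones)
  w <- if (scenario$place_intensity == "centre") {
    cx <- mean(bbox[c(1, 3)]); cy <- mean(bbox[c(2, 4)])
    d <- sqrt((cent$lon - cx)^2 + (cent$lat - cy)^2)
    exp(-d / (0.35 * max(max(d), 1e-12)))
  } else {
    rep(1, nrow(cent))
  }
  home_zone <- sample.int(nrow(cent), n_users, replace = TRUE, prob = w)
  home <- matrix(NA_real_, n_users, 2) # lat, lon
  for (u in seq_len(n_users)) {
    ring <- zones$zones$ring[[home_zone[u]]]
    repeat {
      la <- stats::runif(1, min(ring[, 2]), max(ring[, 2]))
      lo <- stats::runif(1, min(ring[, 1]), max(ring[, 1]))
      if (point_in_ring(lo, la, ring)) break
    }
    home[u, ] <- c(la, lo)
  }

  mover <- matrix(
    stats::rbinom(n_users * n_days, 1L,
                  rep(p_mover, each = n_users)) == 1L,
    n_users, n_days
  )

  meanlog <- log(scenario$dist_median_m)
  user_ids <- sprintf("u%05d", seq_len(n_users))
  pts_user <- list(); pts_time <- list(); pts_lat <- list(); pts_lon <- list()
  tr_rows <- list()
  bi <- 0L

  for (day in seq_len(n_days)) {
    for (u in seq_len(n_users)) {
      if (mover[u, day]) {
        n_trips <- 1L + stats::rpois(1L, scenario$trips_lambda)
        plat <- numeric(n_trips + 1L)
        plon <- numeric(n_trips + 1L)
        plat[1] <- home[u, 1]; plon[1] <- home[u, 2]
        # planted trips must survive place detection: points of two places
        # jittered toward each other can close at most 2*jitter_m of the gap
        d_min <- radius_m + 2 * scenario$jitter_m
        for (t in seq_len(n_trips)) {
          repeat {
            d <- stats::rlnorm(1, meanlog, scenario$dist_sdlog)
            if (d > d_min) break
          }
          ok <- FALSE
          for (try in 1:100) {
            b <- stats::runif(1, 0, 360)
            p <- dest_point(plat[t], plon[t], b, d)
            if (in_bbox(p[1], p[2], bbox)) { ok <- TRUE; break }
          }
          if (!ok) {
            # aim at the bbox centre and shorten until inside
            b <- atan2(mean(bbox[c(1, 3)]) - plon[t],
                       mean(bbox[c(2, 4)]) - plat[t]) * 180 / pi
            repeat {
              p <- dest_point(plat[t], plon[t], b, d)
              if (in_bbox(p[1], p[2], bbox)) break
              d <- max(d * 0.7, d_min * 1.01)
            }
          }
          plat[t + 1L] <- p[1]; plon[t + 1L] <- p[2]
        }
        n_places <- n_trips + 1L
        bi <- bi + 1L
        tr_rows[[bi]] <- data.table::data.table(
          user_id = user_ids[u], date = dates[day],
          trip_index = seq_len(n_trips),
          origin_lat = plat[-n_places], origin_lon = plon[-n_places],
          dest_lat = plat[-1L], dest_lon = plon[-1L],
          distance_m = haversine_m(plat[-n_places], plon[-n_places],
                                   plat[-1L], plon[-1L])
        )
      } else {
        n_places <- 1L
        plat <- home[u, 1]; plon <- home[u, 2]
      }
      npts <- 1L + stats::rpois(n_places, scenario$points_lambda)
      m <- sum(npts)
      jb <- stats::runif(m, 0, 360)
      jd <- stats::runif(m, 0, scenario$jitter_m)
      base_lat <- rep(plat, npts)
      base_lon <- rep(plon, npts)
      jp <- dest_point(base_lat, base_lon, jb, jd)
      out_of_area <- !in_bbox(jp[, 1], jp[, 2], bbox)
      jp[out_of_area, 1] <- base_lat[out_of_area]
      jp[out_of_area, 2] <- base_lon[out_of_area]
      hours <- sample(0:23, m, replace = TRUE, prob = scenario$diurnal_weights)
      secs <- sort(hours * 3600 + stats::runif(m, 0, 3600))
      k <- length(pts_user) + 1L
      pts_user[[k]] <- rep(user_ids[u], m)
      pts_time[[k]] <- civil_time(dates[day], secs, scenario$tz)
      pts_lat[[k]] <- jp[, 1]
      pts_lon[[k]] <- jp[, 2]
    }
  }

  tstamp <- do.call(c, pts_time)
  attr(tstamp, "tzone") <- "UTC"
  points <- tibble::tibble(
    user_id = unlist(pts_user),
    timestamp = tstamp,
    lat = unlist(pts_lat),
    lon = unlist(pts_lon)
  )
  points <- points[order(points$user_id, points$timestamp), ]
  truth_trips <- if (bi > 0) {
    tibble::as_tibble(data.table::rbindlist(tr_rows))
  } else {
    tibble::tibble(
      user_id = character(), date = as.Date(character()), trip_index = integer(),
      origin_lat = numeric(), origin_lon = numeric(),
      dest_lat = numeric(), dest_lon = numeric(), distance_m = numeric()
    )
  }
  truth_movers <- tibble::tibble(
    user_id = rep(user_ids, times = n_days),
    date = rep(dates, each = n_users),
    mover = as.vector(mover)
  )
  list(points = points, truth_trips = truth_trips, truth_movers = truth_movers)
}

#' Case-surface scenario
#'
#' Parameters of the synthetic weekly zone-level case generator: a
#' simultaneous-autoregressive (SAR) latent field with autocorrelation
#' strength `rho`, a linear coupling `coupling_b` to standardized zone
#' attractiveness, a baseline weekly rate, and Gaussian innovation noise.
#'
#' @param rho spatial-autocorrelation strength of the latent field,
#'   `|rho| < 1`.
#' @param coupling_b linear coefficient on standardized attractiveness.
#' @param base_rate mean cases per zone-week, `>= 0`.
#' @param noise_sd innovation SD of the latent field.
#' @param poisson if TRUE, draw Poisson counts around the expectation instead
#'   of deterministic rounding (rounding keeps coupling recovery exact at
#'   small n).
#' @param seed integer seed.
#' @return a `case_scenario` list.
#' @export
case_scenario <- function(rho = 0.6, coupling_b = 1, base_rate = 50,
                          noise_sd = 5, poisson = FALSE, seed = 1L) {
  if (abs(rho) >= 1) stop_mobflow("|rho| must be < 1 (SAR system must be invertible)")
  if (base_rate < 0) stop_mobflow("base_rate must be >= 0")
  structure(
    list(rho = rho, coupling_b = coupling_b, base_rate = base_rate,
         noise_sd = noise_sd, poisson = poisson, seed = as.integer(seed)),
    class = "case_scenario"
  )
}

#' Generate weekly zone-level case counts with known spatial structure
#'
#' For each week, draws a latent field `u` solving `u = rho * W %*% u + eps`
#' (simultaneous-autoregressive construction on the row-standardized queen
#' weights), sets the expectation to
#' `base_rate + coupling_b * z(attractiveness) + u` with population-SD
#' standardized attractiveness, and emits counts by rounding and flooring at
#' zero (or Poisson sampling when the scenario asks for it).
#'
#' @param zones a [zone_system()] (defines the zone universe).
#' @param weights row-standardized [queen_weights()] on `zones`.
#' @param attractiveness long tibble `week_start`, `zone_id`, `share` (zones
#'   absent in a week count as share 0).
#' @param scenario a [case_scenario()].
#' @return a case tibble `zone_id`, `week_start`, `cases`.
#' @export
generate_cases <- function(zones, weights, attractiveness, scenario) {
  stopifnot(inherits(scenario, "case_scenario"))
  ids <- weights$zone_ids
  n <- length(ids)
  weeks <- sort(unique(as.Date(attractiveness$week_start)))
  if (!length(weeks)) stop_mobflow("attractiveness covers no weeks")
  set.seed(scenario$seed)
  A <- diag(n) - scenario$rho * weights$W
  out <- vector("list", length(weeks))
  for (k in seq_along(weeks)) {
    a <- rep(0, n)
    sl <- attractiveness[as.Date(attractiveness$week_start) == weeks[k], ]
    a[match(sl$zone_id, ids)] <- sl$share
    eps <- stats::rnorm(n, 0, scenario$noise_sd)
    u <- solve(A, eps)
    mu <- scenario$base_rate + scenario$coupling_b * zscore_pop(a) + u
    cases <- if (scenario$poisson) {
      stats::rpois(n, pmax(mu, 0))
    } else {
      pmax(0, round(mu))
    }
    out[[k]] <- tibble::tibble(zone_id = ids, week_start = weeks[k],
                               cases = as.integer(cases))
  }
  dplyr::bind_rows(out)
}

#' Write a point table as CSV or JSON-lines
#'
#' Columns `user_id,timestamp,lat,lon` with ISO-8601 UTC timestamps.
#'
#' @param points a point tibble.
#' @param path output path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  df <- data.frame(
    user_id = points$user_id,
    timestamp = format(points$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    lat = points$lat, lon = points$lon
  )
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
    }
  }
  invisible(path)
}

#' Write weekly case counts as CSV
#'
#' Columns `zone_id,week_start,cases`; `week_start` is the ISO date of the
#' week's Monday.
#'
#' @param cases a case tibble from [generate_cases()] or read externally.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cases_csv <- function(cases, path) {
  utils::write.csv(
    data.frame(zone_id = cases$zone_id,
               week_start = format(as.Date(cases$week_start)),
               cases = cases$cases),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read weekly case counts from CSV
#' @param path CSV with columns `zone_id,week_start,cases`.
#' @return a case tibble `zone_id`, `week_start` (Date), `cases` (integer).
#' @export
read_cases_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "character", "integer"))
  required <- c("zone_id", "week_start", "cases")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_mobflow("missing required column(s): ", paste(missing, collapse = ", "))
  }
  tibble::tibble(zone_id = df$zone_id, week_start = as.Date(df$week_start),
                 cases = as.integer(df$cases))
}
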