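#' Great-circle (crow-fly) distance in meters
#'
#' Haversine distance on a sphere of radius 6,371,000 m; vectorized and
#' recycled over its arguments.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees.
#' @return distances in meters.
#' @examples
#' haversine_m(0, 0, 0, 1) # ~111195 m, one degree of longitude at the equator
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371000)
}

# pairwise haversine distance matrix for one small point set
haversine_matrix <- function(lat, lon) {
  n <- length(lat)
  i <- rep(seq_len(n), each = n)
  j <- rep(seq_len(n), times = n)
  matrix(haversine_m(lat[i], lon[i], lat[j], lon[j]), n, n)
}

# Density-based clustering over haversine distances, for the small per-scope
# point sets trip extraction works on. With min_pts = 1 every point is core
# and the clusters are exactly the connected components of the graph linking
# point pairs <= radius_m apart. Returns an integer label per point, 0 = noise
# (possible only when min_pts > 1), labels numbered by first appearance.
cluster_points <- function(lat, lon, radius_m, min_pts = 1) {
  n <- length(lat)
  if (n == 1L) return(if (min_pts <= 1) 1L else 0L)
  adj <- haversine_matrix(lat, lon) <= radius_m
  core <- rowSums(adj) >= min_pts # neighbourhood includes the point itself
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1L)) {
    if (!core[i]) next
    for (j in seq.int(i + 1L, n)) {
      if (core[j] && adj[i, j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  labels <- integer(n)
  roots <- vapply(seq_len(n), find, 1L)
  for (i in seq_len(n)) {
    if (core[i]) labels[i] <- roots[i]
  }
  # border points: non-core within radius of a core point joins the cluster
  # of its lowest-index core neighbour (deterministic)
  for (i in which(!core)) {
    nb <- which(core & adj[i, ])
    if (length(nb)) labels[i] <- roots[nb[1]]
  }
  # renumber by first appearance
  pos <- labels > 0L
  labels[pos] <- match(labels[pos], unique(labels[pos]))
  labels
}

#' Detect activity places by density-based clustering
#'
#' Groups one clustering scope's points (typically a single user's points on
#' one day) into places: clusters of points within `radius_m` of one another.
#' With `min_pts = 1` (the default, suited to sparse social-media streams)
#' this equals the connected components of the graph linking point pairs at
#' most `radius_m` apart. A place is represented by the arithmetic mean of
#' its member coordinates.
#'
#' @param points a tibble/data frame with columns `lat`, `lon` (a point table
#'   works as-is).
#' @param radius_m linkage radius in meters (default 500, a walkable scale).
#' @param min_pts minimum neighbourhood size (self included) for a core
#'   point; default 1.
#' @return a list with `assignment` (integer place label per input point,
#'   0 = noise when `min_pts > 1`) and `places` (tibble `place_id`, `lat`,
#'   `lon`, `n_points`).
#' @export
detect_places <- function(points, radius_m = 500, min_pts = 1) {
  if (!nrow(points)) stop_mobflow("detect_places needs at least one point")
  lab <- cluster_points(points$lat, points$lon, radius_m, min_pts)
  keep <- lab > 0L
  places <- tibble::tibble(
    place_id = sort(unique(lab[keep])),
    lat = as.numeric(tapply(points$lat[keep], lab[keep], mean)),
    lon = as.numeric(tapply(points$lon[keep], lab[keep], mean)),
    n_points = as.integer(table(lab[keep]))
  )
  list(assignment = lab, places = places)
}

# per-(user, day) trip emission: points are chronologically ordered; one trip
# per consecutive pair of points assigned to different places
trip_group <- function(lat, lon, radius_m, min_pts) {
  lab <- cluster_points(lat, lon, radius_m, min_pts)
  keep <- lab > 0L
  lab <- lab[keep]
  lat <- lat[keep]
  lon <- lon[keep]
  if (length(lab) < 2L || length(unique(lab)) < 2L) return(NULL)
  clat <- tapply(lat, lab, mean)
  clon <- tapply(lon, lab, mean)
  i <- which(diff(lab) != 0L)
  o <- as.character(lab[i])
  d <- as.character(lab[i + 1L])
  list(
    origin_lat = as.numeric(clat[o]), origin_lon = as.numeric(clon[o]),
    dest_lat = as.numeric(clat[d]), dest_lon = as.numeric(clon[d]),
    distance_m = haversine_m(clat[o], clon[o], clat[d], clon[d])
  )
}

# per-user scope: one clustering over the user's whole period, trips still
# emitted within single local days
trip_group_user <- function(lat, lon, date, radius_m, min_pts) {
  lab <- cluster_points(lat, lon, radius_m, min_pts)
  keep <- lab > 0L
  lab <- lab[keep]; lat <- lat[keep]; lon <- lon[keep]; date <- date[keep]
  if (length(lab) < 2L) return(NULL)
  clat <- tapply(lat, lab, mean)
  clon <- tapply(lon, lab, mean)
  m <- length(lab)
  i <- which(lab[-m] != lab[-1L] & date[-m] == date[-1L])
  if (!length(i)) return(NULL)
  o <- as.character(lab[i])
  d <- as.character(lab[i + 1L])
  list(
    date = date[i],
    origin_lat = as.numeric(clat[o]), origin_lon = as.numeric(clon[o]),
    dest_lat = as.numeric(clat[d]), dest_lon = as.numeric(clon[d]),
    distance_m = haversine_m(clat[o], clon[o], clat[d], clon[d])
  )
}

#' Extract daily trips from a cleaned point stream
#'
#' For each user and local calendar day, detects that user-day's places with
#' [detect_places()], orders the points chronologically, and emits one trip
#' per consecutive pair of points assigned to different places. Trip distance
#' is the crow-fly distance between the two place centroids. Displacements
#' crossing local midnight are not trips.
#'
#' The default clustering scope is per user-day: a global clustering at a
#' 500 m linkage radius would chain a dense city centre into one giant
#' place, and the jitter the clustering absorbs is a property of one user's
#' posts around one venue. `scope = "user"` instead clusters each user's
#' whole-period points once, sharing places across days.
#'
#' @param points a cleaned point tibble.
#' @param radius_m,min_pts clustering parameters (see [detect_places()]).
#' @param tz IANA timezone defining the local civil day (default
#'   `"Europe/London"`).
#' @param scope `"user-day"` (default) or `"user"` clustering scope.
#' @return a trip tibble: `user_id`, `date`, `origin_lat`, `origin_lon`,
#'   `dest_lat`, `dest_lon`, `distance_m`.
#' @export
extract_daily_trips <- function(points, radius_m = 500, min_pts = 1,
                                tz = "Europe/London",
                                scope = c("user-day", "user")) {
  scope <- match.arg(scope)
  if (!nrow(points)) return(empty_trips())
  dt <- data.table::as.data.table(points)
  timestamp <- user_id <- NULL
  dt[, "date" := as.Date(format(timestamp, "%Y-%m-%d", tz = tz))]
  data.table::setorder(dt, user_id, timestamp)
  trips <- if (scope == "user-day") {
    dt[, if (.N >= 2L) trip_group(.SD$lat, .SD$lon, radius_m, min_pts),
       by = c("user_id", "date")]
  } else {
    dt[, if (.N >= 2L) trip_group_user(.SD$lat, .SD$lon, .SD$date,
                                       radius_m, min_pts),
       by = "user_id"]
  }
  if (!nrow(trips)) return(empty_trips())
  data.table::setcolorder(trips, c("user_id", "date"))
  tibble::as_tibble(trips)
}

empty_trips <- function() {
  tibble::tibble(
    user_id = character(), date = as.Date(character()),
    origin_lat = numeric(), origin_lon = numeric(),
    dest_lat = numeric(), dest_lon = numeric(), distance_m = numeric()
  )
}

#' Daily mobility indices
#'
#' Computes, per local calendar day, the two global mobility indices: the
#' moving-user rate `m_rate` — the fraction of that day's active users
#' (users with at least one point) who made at least one trip — and
#' `avg_dis_m` — the mean over movers of each mover's mean crow-fly trip
#' distance that day (user-weighted, not trip-weighted).
#'
#' @param trips a trip tibble from [extract_daily_trips()].
#' @param points the point tibble the trips were extracted from.
#' @param tz timezone defining the local day; must match the extraction call.
#' @return a tibble `date`, `n_users`, `n_movers`, `m_rate`, `avg_dis_m`
#'   (NA on days without movers), one row per day with at least one point.
#' @export
daily_indices <- function(trips, points, tz = "Europe/London") {
  if (!nrow(points)) {
    return(tibble::tibble(
      date = as.Date(character()), n_users = integer(), n_movers = integer(),
      m_rate = numeric(), avg_dis_m = numeric()
    ))
  }
  pd <- data.table::data.table(
    user_id = points$user_id,
    date = as.Date(format(points$timestamp, "%Y-%m-%d", tz = tz))
  )
  user_id <- date <- distance_m <- NULL
  act <- pd[, list(n_users = data.table::uniqueN(user_id)), by = "date"]
  if (nrow(trips)) {
    td <- data.table::as.data.table(trips)
    per_user <- td[, list(mean_dis = mean(distance_m)), by = c("date", "user_id")]
    mov <- per_user[, list(n_movers = .N, avg_dis_m = mean(mean_dis)), by = "date"]
  } else {
    mov <- data.table::data.table(
      date = as.Date(character()), n_movers = integer(), avg_dis_m = numeric()
    )
  }
  out <- merge(act, mov, by = "date", all.x = TRUE)
  out[is.na(out$n_movers), "n_movers"] <- 0L
  out$m_rate <- out$n_movers / out$n_users
  data.table::setorder(out, date)
  tibble::as_tibble(out[, c("date", "n_users", "n_movers", "m_rate", "avg_dis_m"),
                        with = FALSE])
}

#' Summarize a daily index series
#'
#' Annual/period summary of a [daily_indices()] series. The headline ratio is
#' reported under both conventions — the ratio of daily means
#' (`mean(n_movers) / mean(n_users)`) and the mean of daily ratios
#' (`mean(m_rate)`) — which differ whenever activity varies over days; the
#' ratio-of-means convention is the primary one.
#'
#' @param indices a tibble from [daily_indices()].
#' @return a one-row tibble: `n_days`, `mean_daily_users`,
#'   `mean_daily_movers`, `ratio_of_means`, `mean_of_ratios`,
#'   `mean_avg_dis_m`.
#' @export
summarize_indices <- function(indices) {
  tibble::tibble(
    n_days = nrow(indices),
    mean_daily_users = mean(indices$n_users),
    mean_daily_movers = mean(indices$n_movers),
    ratio_of_means = mean(indices$n_movers) / mean(indices$n_users),
    mean_of_ratios = mean(indices$m_rate, na.rm = TRUE),
    mean_avg_dis_m = mean(indices$avg_dis_m, na.rm = TRUE)
  )
}

#' Classical trend/seasonal decomposition of a daily series
#'
#' Additive moving-average decomposition (trend = centered period-length
#' moving average; seasonal = per-position means of the detrended series,
#' re-centered to sum to zero over one period; residual = remainder), giving
#' a clearer view of trend and weekly seasonality in an index series.
#'
#' @param values numeric series (e.g. daily `m_rate`), length >= 2 * period.
#' @param period seasonal period in observations (default 7, weekly cycle of
#'   a daily series).
#' @param dates optional `Date` vector aligned with `values`.
#' @return a tibble `index`, (`date`,) `observed`, `trend`, `seasonal`,
#'   `residual`; `trend` and `residual` are NA in the half-period edges.
#' @export
decompose_series <- function(values, period = 7, dates = NULL) {
  if (length(values) < 2 * period) {
    stop_mobflow("series must cover at least two full periods")
  }
  dec <- stats::decompose(stats::ts(as.numeric(values), frequency = period),
                          type = "additive")
  out <- tibble::tibble(
    index = seq_along(values),
    observed = as.numeric(dec$x),
    trend = as.numeric(dec$trend),
    seasonal = as.numeric(dec$seasonal),
    residual = as.numeric(dec$random)
  )
  if (!is.null(dates)) {
    out <- tibble::add_column(out, date = as.Date(dates), .after = "index")
  }
  attr(out, "period") <- period
  attr(out, "model") <- "additive"
  out
}
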