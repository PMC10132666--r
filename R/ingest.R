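#' Read a geo-located point stream
#'
#' Reads one record per post — `user_id`, `timestamp`, `lat`, `lon` — from
#' CSV or JSON-lines. Rows with missing or out-of-range coordinates or
#' unparseable timestamps are dropped and counted; a missing required column
#' is a hard error. Timestamps are parsed as UTC (ISO-8601, date-time).
#'
#' @param path file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return a tibble with columns `user_id` (character), `timestamp`
#'   (POSIXct, UTC), `lat`, `lon`, sorted by `(user_id, timestamp)`, with an
#'   attribute `n_dropped` giving the number of invalid rows removed.
#' @export
read_points <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_mobflow("file not found: ", path)
  raw <- if (format == "csv") {
    utils::read.csv(path, colClasses = "character")
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      data.frame(user_id = character(), timestamp = character(),
                 lat = character(), lon = character())
    } else {
      recs <- lapply(lines, jsonlite::fromJSON)
      data.frame(
        user_id = vapply(recs, function(r) as.character(r$user_id %||% NA), ""),
        timestamp = vapply(recs, function(r) as.character(r$timestamp %||% NA), ""),
        lat = vapply(recs, function(r) as.character(r$lat %||% NA), ""),
        lon = vapply(recs, function(r) as.character(r$lon %||% NA), "")
      )
    }
  }
  required <- c("user_id", "timestamp", "lat", "lon")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop_mobflow("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (!nrow(raw)) {
    warning("empty point file: ", path, call. = FALSE)
    return(empty_points())
  }
  ts <- as.POSIXct(strptime(raw$timestamp, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
  alt <- is.na(ts)
  if (any(alt)) {
    ts[alt] <- as.POSIXct(strptime(raw$timestamp[alt], "%Y-%m-%d %H:%M:%OS",
                                   tz = "UTC"))
  }
  lat <- suppressWarnings(as.numeric(raw$lat))
  lon <- suppressWarnings(as.numeric(raw$lon))
  ok <- !is.na(ts) & !is.na(lat) & !is.na(lon) &
    lat >= -90 & lat <= 90 & lon >= -180 & lon <= 180 &
    nzchar(raw$user_id) & !is.na(raw$user_id)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(n_dropped, " invalid row(s) dropped while reading ", path)
  }
  pts <- tibble::tibble(
    user_id = raw$user_id[ok], timestamp = ts[ok], lat = lat[ok], lon = lon[ok]
  )
  pts <- pts[order(pts$user_id, pts$timestamp), ]
  attr(pts, "n_dropped") <- n_dropped
  pts
}

empty_points <- function() {
  tibble::tibble(
    user_id = character(),
    timestamp = as.POSIXct(character(), tz = "UTC"),
    lat = numeric(), lon = numeric()
  )
}

#' Keep only points inside the study area
#'
#' Point-in-polygon crop of a point table to a zone system; boundary points
#' are retained.
#'
#' @param points a point tibble (see [read_points()]).
#' @param zones a [zone_system()].
#' @return the cropped point tibble.
#' @export
filter_bounds <- function(points, zones) {
  if (!nrow(points)) return(points)
  keep <- !is.na(locate_zones(points$lat, points$lon, zones))
  points[keep, ]
}

#' Remove abnormally prolific accounts
#'
#' Accounts posting far more than typical users are likely automated or
#' commercial; users whose total point count over each calendar year exceeds
#' that year's `mean + k * SD` of per-user counts (sample SD, strict
#' inequality) are removed entirely. `k = Inf` disables the filter.
#'
#' @param points a point tibble.
#' @param k SD multiplier above the mean (default 1).
#' @return the filtered point tibble, with attribute `n_users_removed`.
#' @export
remove_abnormal_accounts <- function(points, k = 1) {
  if (!nrow(points) || is.infinite(k)) {
    attr(points, "n_users_removed") <- 0L
    return(points)
  }
  year <- format(points$timestamp, "%Y")
  drop_users <- character(0)
  for (y in unique(year)) {
    cnt <- table(points$user_id[year == y])
    thr <- mean(cnt) + k * stats::sd(cnt)
    if (is.na(thr)) thr <- mean(cnt) # single user: SD undefined, treat as 0
    drop_users <- union(drop_users, names(cnt)[cnt > thr])
  }
  out <- points[!(points$user_id %in% drop_users), ]
  attr(out, "n_users_removed") <- length(drop_users)
  out
}

#' Remove static users
#'
#' Users whose every point carries one exact coordinate pair cannot generate
#' trips and are treated as static (screens, bots, fixed venues); all their
#' rows are removed.
#'
#' @param points a point tibble.
#' @return the filtered point tibble, with attribute `n_users_removed`.
#' @export
remove_static_users <- function(points) {
  if (!nrow(points)) {
    attr(points, "n_users_removed") <- 0L
    return(points)
  }
  dt <- data.table::as.data.table(points)
  lat <- lon <- user_id <- NULL
  st <- dt[, list(static = data.table::uniqueN(paste(lat, lon)) == 1L), by = user_id]
  drop_users <- st$user_id[st$static]
  out <- points[!(points$user_id %in% drop_users), ]
  attr(out, "n_users_removed") <- length(drop_users)
  out
}

#' Clean a point stream
#'
#' Applies the standard cleaning sequence: crop to the study area, remove
#' abnormal accounts, remove static users. Each stage is idempotent.
#'
#' @param points a point tibble.
#' @param zones a [zone_system()].
#' @param k_sd SD multiplier for [remove_abnormal_accounts()]; `Inf` disables.
#' @return a list with `points` (the cleaned tibble) and `report` (a
#'   `cleaning_report`: input/stage counts and the thresholds used).
#' @export
clean_points <- function(points, zones, k_sd = 1) {
  n_input <- nrow(points)
  pts <- filter_bounds(points, zones)
  n_after_bbox <- nrow(pts)
  pts <- remove_abnormal_accounts(pts, k = k_sd)
  n_abn <- attr(pts, "n_users_removed")
  pts <- remove_static_users(pts)
  n_static <- attr(pts, "n_users_removed")
  report <- structure(
    list(
      n_input = n_input,
      n_after_bbox = n_after_bbox,
      n_users_removed_abnormal = n_abn,
      n_static_users_removed = n_static,
      n_output = nrow(pts),
      thresholds = list(k_sd = k_sd)
    ),
    class = "cleaning_report"
  )
  list(points = pts, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n")
  cat("  input rows:          ", x$n_input, "\n")
  cat("  after study-area crop:", x$n_after_bbox, "\n")
  cat("  abnormal users removed:", x$n_users_removed_abnormal,
      " (k_sd = ", x$thresholds$k_sd, ")\n", sep = "")
  cat("  static users removed: ", x$n_static_users_removed, "\n")
  cat("  output rows:          ", x$n_output, "\n")
  invisible(x)
}

#' Write a cleaning report as JSON
#' @param report a `cleaning_report` from [clean_points()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
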