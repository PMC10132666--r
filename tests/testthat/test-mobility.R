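test_that("haversine distance matches the closed form and is symmetric", {
  expect_equal(haversine_m(51.5, -0.1, 51.5, -0.1), 0)
  # one degree along the equator: 2*pi*R/360
  expect_equal(haversine_m(0, 0, 0, 1), 2 * pi * 6371000 / 360, tolerance = 1 / 111195)
  set.seed(1)
  a_lat <- runif(100, -80, 80); a_lon <- runif(100, -180, 180)
  b_lat <- runif(100, -80, 80); b_lon <- runif(100, -180, 180)
  expect_equal(haversine_m(a_lat, a_lon, b_lat, b_lon),
               haversine_m(b_lat, b_lon, a_lat, a_lon))
})

test_that("place detection equals connected components at the linkage radius", {
  # two points 600 m apart: two places
  p2 <- tibble::tibble(lat = c(51.5, 51.5 + lat_offset(600)), lon = c(-0.1, -0.1))
  expect_equal(nrow(detect_places(p2, radius_m = 500)$places), 2)

  # chain at 0, 400, 800 m: transitive linkage gives one place
  chain <- tibble::tibble(lat = 51.5 + lat_offset(c(0, 400, 800)), lon = rep(-0.1, 3))
  res <- detect_places(chain, radius_m = 500)
  expect_equal(nrow(res$places), 1)
  expect_equal(res$assignment, components_bf(chain$lat, chain$lon, 500))

  # 20 jittered points within 100 m: one place, centroid inside the disc
  set.seed(3)
  jit <- tibble::tibble(
    lat = 51.5 + lat_offset(runif(20, -100, 100)),
    lon = -0.1 + lat_offset(runif(20, -100, 100)) / cos(51.5 * pi / 180)
  )
  resj <- detect_places(jit, radius_m = 500)
  expect_equal(nrow(resj$places), 1)
  expect_lt(haversine_m(resj$places$lat, resj$places$lon, 51.5, -0.1), 150)

  # property: on random configurations, min_pts = 1 assignment matches the
  # brute-force component labelling, and cross-place pairs are > radius apart
  for (s in 1:10) {
    set.seed(s)
    n <- sample(3:15, 1)
    lat <- 51.5 + lat_offset(runif(n, 0, 3000))
    lon <- -0.1 + lat_offset(runif(n, 0, 3000))
    got <- detect_places(tibble::tibble(lat = lat, lon = lon), radius_m = 500)
    oracle <- components_bf(lat, lon, 500)
    expect_equal(got$assignment, oracle)
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        if (got$assignment[i] != got$assignment[j]) {
          expect_gt(haversine_m(lat[i], lon[i], lat[j], lon[j]), 500)
        }
      }
    }
  }
})

test_that("DBSCAN with min_pts > 1 separates core, border and noise points", {
  # 3 clustered points (each sees the other two) + 1 far singleton
  lat <- 51.5 + lat_offset(c(0, 100, 200, 5000))
  lon <- rep(-0.1, 4)
  res <- detect_places(tibble::tibble(lat = lat, lon = lon),
                       radius_m = 500, min_pts = 3)
  expect_equal(res$assignment, c(1L, 1L, 1L, 0L)) # singleton is noise
  expect_equal(nrow(res$places), 1)
})

test_that("daily trips are consecutive place changes within a local day", {
  d600 <- lat_offset(600)
  # P1 09:00 -> P2 12:00 -> P1 18:00: two trips, there and back
  pts <- make_points(
    rep("u", 3),
    c("2019-03-04 09:00:00", "2019-03-04 12:00:00", "2019-03-04 18:00:00"),
    c(51.5, 51.5 + d600, 51.5), rep(-0.1, 3)
  )
  tr <- extract_daily_trips(pts, tz = "UTC")
  expect_equal(nrow(tr), 2)
  expect_equal(tr$origin_lat, c(51.5, 51.5 + d600))
  expect_equal(tr$dest_lat, c(51.5 + d600, 51.5))
  expect_equal(tr$distance_m, rep(haversine_m(51.5, -0.1, 51.5 + d600, -0.1), 2),
               tolerance = 1e-9)

  # two posts from the same building (80 m apart): one place, no trip
  near <- make_points(rep("u", 2),
                      c("2019-03-04 09:00:00", "2019-03-04 17:00:00"),
                      c(51.5, 51.5 + lat_offset(80)), rep(-0.1, 2))
  expect_equal(nrow(extract_daily_trips(near, tz = "UTC")), 0)

  # 23:00 day 1 -> 01:00 day 2 crosses local midnight: no daily trip
  cross <- make_points(rep("u", 2),
                       c("2019-03-04 23:00:00", "2019-03-05 01:00:00"),
                       c(51.5, 51.5 + d600), rep(-0.1, 2))
  expect_equal(nrow(extract_daily_trips(cross, tz = "UTC")), 0)
})

test_that("per-user clustering scope shares places across days", {
  d600 <- lat_offset(600)
  pts <- make_points(
    rep("u", 4),
    c("2019-03-04 09:00:00", "2019-03-04 18:00:00",
      "2019-03-05 09:00:00", "2019-03-05 18:00:00"),
    c(51.5, 51.5 + d600, 51.5, 51.5 + d600), rep(-0.1, 4)
  )
  per_day <- extract_daily_trips(pts, tz = "UTC", scope = "user-day")
  per_user <- extract_daily_trips(pts, tz = "UTC", scope = "user")
  expect_equal(nrow(per_day), 2)
  expect_equal(nrow(per_user), 2)
  # same-day pairs only: the overnight return is never a trip
  expect_equal(as.character(per_user$date), c("2019-03-04", "2019-03-05"))
})

test_that("trip counts equal chronological place changes (conservation)", {
  set.seed(11)
  days <- as.Date("2019-03-04") + 0:4
  rows <- list()
  for (u in 1:8) {
    for (d in days) {
      n <- sample(1:5, 1)
      rows[[length(rows) + 1]] <- make_points(
        rep(sprintf("u%d", u), n),
        as.POSIXct(as.Date(d, origin = "1970-01-01"), tz = "UTC") +
          sort(sample(3600 * 6:22, n)) + runif(n, 0, 3000),
        51.5 + lat_offset(runif(n, 0, 4000)),
        -0.1 + lat_offset(runif(n, 0, 4000))
      )
    }
  }
  pts <- dplyr::bind_rows(rows)
  tr <- extract_daily_trips(pts, tz = "UTC")
  # oracle: per user-day, label points by brute-force components and count
  # label changes along the chronological sequence
  expected <- 0L
  pts$date <- as.Date(format(pts$timestamp, tz = "UTC"))
  for (key in split(pts[order(pts$user_id, pts$timestamp), ],
                    paste(pts$user_id, pts$date)[order(pts$user_id, pts$timestamp)])) {
    if (nrow(key) < 2) next
    lab <- components_bf(key$lat, key$lon, 500)
    expected <- expected + sum(diff(lab) != 0)
  }
  expect_equal(nrow(tr), expected)
  expect_true(all(tr$distance_m > 0))
})

test_that("daily indices follow the moving-user rate and user-weighted distance", {
  day <- as.Date("2019-03-04")
  # 10 active users, 3 movers
  pts <- make_points(sprintf("u%02d", 1:10),
                     rep("2019-03-04 09:00:00", 10),
                     rep(51.5, 10), seq(-0.1, -0.01, length.out = 10))
  trips <- tibble::tibble(
    user_id = c("u01", "u02", "u03"), date = day,
    origin_lat = 51.5, origin_lon = -0.1, dest_lat = 51.6, dest_lon = -0.1,
    distance_m = c(500, 800, 1200)
  )
  ix <- daily_indices(trips, pts, tz = "UTC")
  expect_equal(ix$n_users, 10)
  expect_equal(ix$n_movers, 3)
  expect_equal(ix$m_rate, 0.3)

  # avg_dis is the mean over movers of per-user mean distances:
  # one mover with trips 1000 and 3000 -> 2000
  t1 <- tibble::tibble(user_id = "u01", date = day,
                       origin_lat = 51.5, origin_lon = -0.1,
                       dest_lat = 51.6, dest_lon = -0.1,
                       distance_m = c(1000, 3000))
  expect_equal(daily_indices(t1, pts, tz = "UTC")$avg_dis_m, 2000)
  # two movers with per-user means 1000 and 3000 -> 2000 (user-weighted,
  # even though u02 made three trips)
  t2 <- tibble::tibble(user_id = c("u01", "u02", "u02", "u02"), date = day,
                       origin_lat = 51.5, origin_lon = -0.1,
                       dest_lat = 51.6, dest_lon = -0.1,
                       distance_m = c(1000, 3000, 3000, 3000))
  expect_equal(daily_indices(t2, pts, tz = "UTC")$avg_dis_m, 2000)

  # day without movers: m_rate 0, avg_dis absent
  ix0 <- daily_indices(empty <- trips[0, ], pts, tz = "UTC")
  expect_equal(ix0$m_rate, 0)
  expect_true(is.na(ix0$avg_dis_m))
})

test_that("classical decomposition recovers planted trend and seasonality", {
  # constant series: zero seasonal and residual
  const <- decompose_series(rep(5, 28), period = 7)
  expect_equal(const$seasonal, rep(0, 28))
  expect_equal(const$residual[!is.na(const$residual)],
               rep(0, sum(!is.na(const$residual))))

  # linear trend + fixed weekly pattern, no noise: exact recovery
  pattern <- c(0.03, -0.01, -0.02, 0, 0.01, 0.02, -0.03)
  n <- 70
  trend <- 0.2 + 0.001 * seq_len(n)
  x <- trend + rep_len(pattern, n)
  dec <- decompose_series(x, period = 7)
  expect_equal(dec$seasonal, rep_len(pattern, n), tolerance = 1e-9)
  core <- !is.na(dec$trend)
  expect_equal(dec$trend[core], trend[core], tolerance = 1e-9)
  # additivity and zero-sum seasonal over one period
  expect_equal(dec$observed[core],
               (dec$trend + dec$seasonal + dec$residual)[core])
  expect_equal(sum(dec$seasonal[1:7]), 0, tolerance = 1e-12)

  expect_error(decompose_series(rnorm(10), period = 7), "two full periods")
})

test_that("a mobility shock shows up in the decomposed m_rate trend", {
  z <- generate_zones(5, 5, 0.03, origin = c(51.3, -0.3))
  sc <- activity_scenario(
    n_users = 250, n_days = 28,
    p_mover = c(rep(0.4, 14), rep(0.1, 14)), # step change mid-window
    seed = 21
  )
  st <- generate_activity_stream(z, sc)
  tr <- extract_daily_trips(st$points)
  ix <- daily_indices(tr, st$points)
  dec <- decompose_series(ix$m_rate, period = 7, dates = ix$date)
  pre <- mean(dec$trend[5:10], na.rm = TRUE)
  post <- mean(dec$trend[19:24], na.rm = TRUE)
  expect_lt(post, pre - 0.15)
})

test_that("index summaries expose both ratio conventions", {
  ix <- tibble::tibble(
    date = as.Date("2019-01-07") + 0:1,
    n_users = c(100, 300), n_movers = c(20, 30),
    m_rate = c(0.2, 0.1), avg_dis_m = c(4000, 6000)
  )
  s <- summarize_indices(ix)
  expect_equal(s$ratio_of_means, 25 / 200)
  expect_equal(s$mean_of_ratios, 0.15)
  expect_equal(s$mean_avg_dis_m, 5000)
})
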