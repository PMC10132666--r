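test_that("queen contiguity on grids has the expected neighbour counts", {
  z <- generate_zones(3, 3, 0.05, origin = c(51, 0))
  w <- queen_weights(z)
  nn <- stats::setNames(lengths(w$nb), w$zone_ids)
  expect_equal(unname(nn["Z_1_1"]), 3) # corner
  expect_equal(unname(nn["Z_1_2"]), 5) # edge
  expect_equal(unname(nn["Z_2_2"]), 8) # centre
  expect_equal(w$A, t(w$A)) # adjacency symmetric
  expect_equal(unname(rowSums(w$W)), rep(1, 9)) # row-standardized

  w2 <- queen_weights(generate_zones(1, 2, 0.05, origin = c(51, 0)))
  expect_equal(unname(lengths(w2$nb)), c(1, 1))
  expect_equal(unname(w2$W[1, 2]), 1.0)

  for (dims in list(c(2, 4), c(4, 2), c(5, 5))) {
    wr <- queen_weights(generate_zones(dims[1], dims[2], 0.03, c(50, 1)))
    expect_equal(wr$A, t(wr$A))
  }
})

test_that("global Moran's I matches direct evaluation and the brute-force oracle", {
  # two mutual neighbours with x = (1, -1): I = -1 by direct formula
  z2 <- generate_zones(1, 2, 0.05, origin = c(51, 0))
  w2 <- queen_weights(z2)
  m <- morans_i(c(1, -1), w2, n_perm = 19, seed = 1)
  expect_equal(m$statistic, -1)
  expect_equal(m$expectation, -1)

  # vectorized implementation vs naive double loop, 25-zone grid
  z <- generate_zones(5, 5, 0.05, origin = c(51, 0))
  w <- queen_weights(z)
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(25)
    expect_equal(morans_i(x, w, n_perm = 9, seed = s)$statistic,
                 moran_bf(x, w$W), tolerance = 1e-12)
  }

  # smooth gradient field on a 6x6 grid: strong positive autocorrelation
  z6 <- generate_zones(6, 6, 0.05, origin = c(51, 0))
  w6 <- queen_weights(z6)
  grad <- rep(1:6, each = 6) + rep(1:6, 6) / 2
  mg <- morans_i(grad, w6, n_perm = 199, seed = 7)
  expect_gt(mg$statistic, 0)
  expect_lte(mg$p_value, 0.05)

  expect_error(morans_i(rep(3, 25), w), "constant")

  # fixed seed reproduces the permutation p-value exactly
  x <- rnorm(25)
  expect_identical(morans_i(x, w, n_perm = 99, seed = 5)$p_value,
                   morans_i(x, w, n_perm = 99, seed = 5)$p_value)
})

test_that("local Moran's I matches its oracle and aggregates to the global I", {
  z <- generate_zones(5, 5, 0.05, origin = c(51, 0))
  w <- queen_weights(z)
  set.seed(2)
  x <- rnorm(25)
  loc <- local_morans(x, w, n_perm = 49, seed = 2)
  expect_equal(loc$local_i, local_moran_bf(x, w$W), tolerance = 1e-12)
  # scaling identity: global I = sum(local_i) / S0 (population-z inputs)
  expect_equal(morans_i(x, w, n_perm = 9, seed = 1)$statistic,
               sum(loc$local_i) / w$S0, tolerance = 1e-12)

  # hot 2x2 block in an otherwise flat-but-noisy 6x6 grid: block zones HH
  # and significant
  z6 <- generate_zones(6, 6, 0.05, origin = c(51, 0))
  w6 <- queen_weights(z6)
  set.seed(4)
  field <- rnorm(36, 0, 0.05)
  block <- which(rep(1:6, 6) %in% 3:4 & rep(1:6, each = 6) %in% 3:4)
  field[block] <- field[block] + 3
  loc6 <- local_morans(field, w6, n_perm = 199, seed = 4)
  expect_true(all(loc6$quadrant[block] == "HH"))
  expect_true(all(loc6$significant[block]))

  expect_error(local_morans(rep(1, 25), w), "constant")
})

test_that("bivariate Moran's I reduces to the univariate case and is calibrated", {
  z <- generate_zones(5, 5, 0.05, origin = c(51, 0))
  w <- queen_weights(z)
  set.seed(6)
  x <- rnorm(25)
  uni <- morans_i(x, w, n_perm = 9, seed = 1)$statistic
  expect_equal(bivariate_morans_i(x, x, w, n_perm = 9, seed = 1)$statistic,
               uni, tolerance = 1e-12)
  expect_equal(bivariate_morans_i(x, -x, w, n_perm = 9, seed = 1)$statistic,
               -uni, tolerance = 1e-12)

  # brute-force oracle agreement
  for (s in 1:5) {
    set.seed(s + 10)
    a <- rnorm(25); b <- rnorm(25)
    expect_equal(bivariate_morans_i(a, b, w, n_perm = 9, seed = s)$statistic,
                 bivar_moran_bf(a, b, w$W), tolerance = 1e-12)
  }

  # type-I calibration under independent fields: rejection near alpha
  z6 <- generate_zones(6, 6, 0.05, origin = c(51, 0))
  w6 <- queen_weights(z6)
  rej <- 0
  for (s in 1:50) {
    set.seed(s)
    a <- rnorm(36); b <- rnorm(36)
    if (bivariate_morans_i(a, b, w6, n_perm = 199, seed = s)$p_value <= 0.05) {
      rej <- rej + 1
    }
  }
  # 3 binomial SDs above alpha * 50 = 2.5
  expect_lte(rej, 2.5 + 3 * sqrt(50 * 0.05 * 0.95))

  # local bivariate matches its definitional oracle
  set.seed(30)
  a <- rnorm(25); b <- rnorm(25)
  locb <- local_bivariate_morans(a, b, w, n_perm = 49, seed = 3)
  za <- zstd(a); zb <- zstd(b)
  expect_equal(locb$local_i, za * as.numeric(w$W %*% zb), tolerance = 1e-12)
})

test_that("the weekly correlation suite tracks planted coupling", {
  z <- generate_zones(12, 12, 0.02, origin = c(51.2, -0.5))
  w <- queen_weights(z)
  weeks <- week_index("2020-03-02", "2020-09-21") # 30 weeks
  set.seed(8)
  # spatially smooth attractiveness: centre-weighted gradient with mild
  # weekly noise (bivariate Moran can only see coupling through a spatially
  # structured mobility surface)
  cen <- zone_centroids(z)
  g <- exp(-((cen$lat - mean(cen$lat))^2 + (cen$lon - mean(cen$lon))^2) /
             (2 * 0.06^2))
  shares <- prop.table(matrix(g * rgamma(144 * 30, 20, 20), 144), 2)
  attr_wk <- tibble::tibble(
    week_start = rep(weeks, each = 144),
    zone_id = rep(zone_ids(z), 30),
    share = as.vector(shares)
  )
  cs0 <- generate_cases(z, w, attr_wk,
                        case_scenario(rho = 0, coupling_b = 0, base_rate = 50,
                                      noise_sd = 5, seed = 12))
  suite0 <- weekly_correlation_suite(attr_wk, cs0, w, n_perm = 49, seed = 1)
  expect_equal(nrow(suite0), 30)
  # no coupling: aspatial correlation fluctuates around zero
  expect_lt(mean(abs(suite0$pearson_r)), 0.1)
  expect_lt(abs(median(suite0$bivar_moran)), 0.1)

  # strong positive coupling: bivariate Moran clearly above the null run
  cs5 <- generate_cases(z, w, attr_wk,
                        case_scenario(rho = 0, coupling_b = 25, base_rate = 50,
                                      noise_sd = 5, seed = 12))
  suite5 <- weekly_correlation_suite(attr_wk, cs5, w, n_perm = 49, seed = 1)
  expect_gt(median(suite5$bivar_moran), median(suite0$bivar_moran))
  expect_gt(median(suite5$bivar_moran), 0)
  expect_gt(median(suite5$pearson_r), 0.5)

  # a constant-cases week yields NA markers, not a crash
  cs_const <- cs0
  cs_const$cases[cs_const$week_start == weeks[3]] <- 10L
  suite_c <- weekly_correlation_suite(attr_wk, cs_const, w, n_perm = 49, seed = 1)
  expect_true(is.na(suite_c$pearson_r[3]))
  expect_true(is.na(suite_c$moran_cases[3]))
  expect_false(anyNA(suite_c$pearson_r[-3]))

  expect_error(
    weekly_correlation_suite(attr_wk,
                             dplyr::mutate(cs0, week_start = week_start + 700),
                             w),
    "overlapping"
  )
})

test_that("zones missing cases are excluded with re-standardized weights", {
  z <- generate_zones(4, 4, 0.05, origin = c(51, 0))
  w <- queen_weights(z)
  weeks <- week_index("2020-03-02", "2020-03-02")
  set.seed(3)
  attr_wk <- tibble::tibble(week_start = weeks, zone_id = zone_ids(z),
                            share = prop.table(runif(16)))
  cs <- generate_cases(z, w, attr_wk, case_scenario(rho = 0.4, seed = 5))
  cs_missing <- cs[cs$zone_id != "Z_1_1", ]
  expect_message(
    suite <- weekly_correlation_suite(attr_wk, cs_missing, w, n_perm = 49,
                                      seed = 2),
    "missing cases"
  )
  expect_equal(suite$n_zones, 15)
  sub <- subset_weights(w, setdiff(zone_ids(z), "Z_1_1"))
  expect_equal(unname(rowSums(sub$W)), rep(1, 15))
})

test_that("period-level suite relates attractiveness change to accumulated cases", {
  z <- generate_zones(6, 6, 0.05, origin = c(51, 0))
  w <- queen_weights(z)
  weeks <- week_index("2020-03-02", "2020-04-20")
  set.seed(14)
  attr_wk <- tibble::tibble(
    week_start = rep(weeks, each = 36),
    zone_id = rep(zone_ids(z), length(weeks)),
    share = as.vector(prop.table(matrix(rgamma(36 * length(weeks), 2), 36), 2))
  )
  cs <- generate_cases(z, w, attr_wk, case_scenario(rho = 0.3, seed = 9))
  diffs <- tibble::tibble(period = "win", zone_id = zone_ids(z),
                          diff = rnorm(36, 0, 0.01))
  out <- period_correlation_suite(diffs, cs, w,
                                  periods = list(win = c("2020-03-02",
                                                         "2020-04-20")),
                                  n_perm = 99, seed = 4)
  expect_equal(nrow(out), 1)
  expect_false(anyNA(out$moran_cases))
  # accumulated cases of a rho > 0 surface stay positively autocorrelated
  expect_gt(out$moran_cases, -0.2)
})
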