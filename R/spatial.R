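#' First-order queen contiguity weights
#'
#' Zones sharing at least one boundary point are neighbours. Contiguity is
#' detected through shared polygon vertices (coordinates rounded to 1e-9
#' degrees), which is exact for the grid tessellations this package
#' generates and for any zone system whose shared boundary points are
#' vertices of both polygons. Weights are row-standardized; zones without
#' neighbours (islands) get zero rows and are reported.
#'
#' @param zones a [zone_system()].
#' @return a `spatial_weights`: list with `zone_ids`, `nb` (neighbour index
#'   list), `A` (binary adjacency matrix), `W` (row-standardized weight
#'   matrix), `S0` (sum of all weights) and `islands` (zone ids with no
#'   neighbours).
#' @export
queen_weights <- function(zones) {
  ids <- zones$zones$zone_id
  n <- length(ids)
  vkey <- function(ring) {
    v <- ring[-nrow(ring), , drop = FALSE]
    sprintf("%.9f|%.9f", v[, 1], v[, 2])
  }
  keys <- lapply(zones$zones$ring, vkey)
  vert <- data.frame(
    key = unlist(keys),
    zone = rep(seq_len(n), vapply(keys, length, 1L))
  )
  vert <- unique(vert)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (grp in split(vert$zone, vert$key)) {
    if (length(grp) > 1) {
      for (i in grp) A[i, setdiff(grp, i)] <- 1
    }
  }
  rs <- rowSums(A)
  W <- A / ifelse(rs == 0, 1, rs)
  islands <- ids[rs == 0]
  if (length(islands)) {
    message(length(islands), " island zone(s) with no neighbours: ",
            paste(utils::head(islands, 5), collapse = ", "))
  }
  structure(
    list(
      zone_ids = ids,
      nb = stats::setNames(apply(A > 0, 1, which, simplify = FALSE), ids),
      A = A, W = W, S0 = sum(W), islands = islands
    ),
    class = "spatial_weights"
  )
}

#' @export
print.spatial_weights <- function(x, ...) {
  nn <- lengths(x$nb)
  cat("<spatial_weights> ", length(x$zone_ids),
      " zones, first-order queen contiguity, row-standardized; ",
      "neighbours per zone: ", min(nn), "-", max(nn), sep = "")
  if (length(x$islands)) cat("; ", length(x$islands), " island(s)", sep = "")
  cat("\n")
  invisible(x)
}

#' Restrict spatial weights to a subset of zones
#'
#' Drops the other zones from the adjacency and re-standardizes rows (used
#' when a week's case table misses some zones).
#'
#' @param weights a [queen_weights()] object.
#' @param ids zone ids to keep.
#' @return a `spatial_weights` on the subset.
#' @export
subset_weights <- function(weights, ids) {
  keep <- weights$zone_ids %in% ids
  A <- weights$A[keep, keep, drop = FALSE]
  rs <- rowSums(A)
  W <- A / ifelse(rs == 0, 1, rs)
  kept_ids <- weights$zone_ids[keep]
  structure(
    list(
      zone_ids = kept_ids,
      nb = stats::setNames(apply(A > 0, 1, which, simplify = FALSE), kept_ids),
      A = A, W = W, S0 = sum(W), islands = kept_ids[rs == 0]
    ),
    class = "spatial_weights"
  )
}

check_moran_input <- function(x, weights) {
  n <- length(weights$zone_ids)
  if (length(x) != n) stop_mobflow("x must have one value per zone")
  if (n < 2) stop_mobflow("need at least 2 zones")
  if (weights$S0 <= 0) stop_mobflow("weights have no neighbour structure")
  if (stats::var(x) == 0) {
    stop_mobflow("Moran statistics are undefined for a constant variable")
  }
  invisible(n)
}

moran_stat <- function(x, W, S0) {
  zc <- x - mean(x)
  n <- length(x)
  (n / S0) * as.numeric(zc %*% W %*% zc) / sum(zc^2)
}

new_moran_result <- function(statistic, expectation, p, n_perm, seed, kind) {
  structure(
    list(statistic = statistic, expectation = expectation, p_value = p,
         n_perm = n_perm, seed = seed, kind = kind),
    class = "moran_result"
  )
}

#' @export
print.moran_result <- function(x, ...) {
  cat("<moran_result> ", x$kind, " Moran's I = ", sprintf("%.4f", x$statistic),
      " (E[I] = ", sprintf("%.4f", x$expectation),
      "), permutation p = ", sprintf("%.4g", x$p_value),
      " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

perm_pvalue <- function(obs, perms, center) {
  (1 + sum(abs(perms - center) >= abs(obs - center) - 1e-14)) /
    (length(perms) + 1)
}

#' Global Moran's I with permutation inference
#'
#' `I = (n/S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`.
#' Significance comes from random relabelling of the values over the zones:
#' a two-sided pseudo p-value `(1 + #as-extreme) / (n_perm + 1)`, extremeness
#' measured as distance from the null expectation `-1/(n-1)`.
#'
#' @param x numeric vector, one value per zone of `weights` (same order).
#' @param weights a [queen_weights()] object.
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed for the permutation draw.
#' @return a `moran_result`.
#' @export
morans_i <- function(x, weights, n_perm = 999, seed = NULL) {
  n <- check_moran_input(x, weights)
  obs <- moran_stat(x, weights$W, weights$S0)
  e_i <- -1 / (n - 1)
  if (!is.null(seed)) set.seed(seed)
  perms <- vapply(seq_len(n_perm), function(b) {
    moran_stat(sample(x), weights$W, weights$S0)
  }, numeric(1))
  new_moran_result(obs, e_i, perm_pvalue(obs, perms, e_i), n_perm, seed,
                   "global")
}

# conditional permutation of a lag: for each zone, neighbour values are
# drawn (without replacement, per permutation) from the other zones' values
conditional_lag_perms <- function(z_other, wi, n_perm) {
  ki <- length(wi)
  vapply(seq_len(n_perm), function(b) {
    sum(wi * z_other[sample.int(length(z_other), ki)])
  }, numeric(1))
}

local_moran_core <- function(zx, weights, n_perm, seed, alpha, z_for_lag) {
  n <- length(zx)
  lag <- as.numeric(weights$W %*% z_for_lag)
  local_i <- zx * lag
  if (!is.null(seed)) set.seed(seed)
  p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nbi <- weights$nb[[i]]
    if (!length(nbi)) next
    wi <- weights$W[i, nbi]
    perms <- zx[i] * conditional_lag_perms(z_for_lag[-i], wi, n_perm)
    p[i] <- perm_pvalue(local_i[i], perms, mean(perms))
  }
  quadrant <- rep(NA_character_, n)
  def <- zx != 0 & lag != 0
  quadrant[def & zx > 0 & lag > 0] <- "HH"
  quadrant[def & zx < 0 & lag < 0] <- "LL"
  quadrant[def & zx > 0 & lag < 0] <- "HL"
  quadrant[def & zx < 0 & lag > 0] <- "LH"
  tibble::tibble(
    zone_id = weights$zone_ids, local_i = local_i, z = zx, lag = lag,
    quadrant = quadrant, p_value = p,
    significant = !is.na(p) & p <= alpha & !is.na(quadrant)
  )
}

#' Local Moran's I (LISA) with conditional permutation inference
#'
#' `I_i = z_i * sum_j w_ij z_j` with population-SD standardized values.
#' Quadrant labels (HH hot spots, LL cold spots, HL/LH outliers) come from
#' the signs of `z_i` and its spatial lag; per-zone p-values from
#' conditional permutation (the zone's own value held fixed, neighbour
#' values drawn from the remaining zones).
#'
#' @inheritParams morans_i
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @return a tibble `zone_id`, `local_i`, `z`, `lag`, `quadrant`, `p_value`,
#'   `significant`.
#' @export
local_morans <- function(x, weights, n_perm = 999, seed = NULL, alpha = 0.05) {
  check_moran_input(x, weights)
  z <- zscore_pop(x)
  local_moran_core(z, weights, n_perm, seed, alpha, z_for_lag = z)
}

#' Global bivariate Moran's I
#'
#' `I_xy = (n/S0) * sum_ij w_ij z_x,i z_y,j / sum_i z_x,i^2` with
#' population-SD z-standardized variables: the degree to which high values
#' of `x` at a zone co-occur with high values of `y` at its neighbours. The
#' permutation null relabels `y` over the zones with `x` held fixed.
#'
#' @param x,y numeric vectors aligned with `weights$zone_ids`.
#' @inheritParams morans_i
#' @return a `moran_result`.
#' @export
bivariate_morans_i <- function(x, y, weights, n_perm = 999, seed = NULL) {
  n <- check_moran_input(x, weights)
  check_moran_input(y, weights)
  zx <- zscore_pop(x)
  zy <- zscore_pop(y)
  stat <- function(zyb) (n / weights$S0) *
    as.numeric(zx %*% weights$W %*% zyb) / sum(zx^2)
  obs <- stat(zy)
  if (!is.null(seed)) set.seed(seed)
  perms <- vapply(seq_len(n_perm), function(b) stat(sample(zy)), numeric(1))
  new_moran_result(obs, 0, perm_pvalue(obs, perms, 0), n_perm, seed,
                   "bivariate")
}

#' Local bivariate Moran's I
#'
#' `I_i = z_x,i * sum_j w_ij z_y,j`; conditional permutation of `y` over the
#' other zones, `x` held fixed.
#'
#' @inheritParams bivariate_morans_i
#' @param alpha significance level for the `significant` flag.
#' @return a tibble as in [local_morans()].
#' @export
local_bivariate_morans <- function(x, y, weights, n_perm = 999, seed = NULL,
                                   alpha = 0.05) {
  check_moran_input(x, weights)
  check_moran_input(y, weights)
  zx <- zscore_pop(x)
  zy <- zscore_pop(y)
  local_moran_core(zx, weights, n_perm, seed, alpha, z_for_lag = zy)
}

suite_row <- function(a, cs, w, n_perm, seed, alpha) {
  degenerate <- stats::var(cs) == 0 || stats::var(a) == 0
  if (degenerate) {
    return(list(pearson_r = NA_real_, moran_cases = NA_real_,
                moran_cases_p = NA_real_, bivar_moran = NA_real_,
                bivar_moran_p = NA_real_, n_sig_local = NA_integer_))
  }
  mi <- morans_i(cs, w, n_perm = n_perm, seed = seed)
  bi <- bivariate_morans_i(a, cs, w, n_perm = n_perm, seed = seed + 1L)
  loc <- local_bivariate_morans(a, cs, w, n_perm = n_perm, seed = seed + 2L,
                                alpha = alpha)
  list(
    pearson_r = stats::cor(a, cs),
    moran_cases = mi$statistic, moran_cases_p = mi$p_value,
    bivar_moran = bi$statistic, bivar_moran_p = bi$p_value,
    n_sig_local = sum(loc$significant)
  )
}

#' Weekly suite of mobility-case correlation measures
#'
#' For each week present in both sources, computes the four measures
#' relating zone attractiveness to reported cases: aspatial Pearson
#' correlation, global Moran's I of the cases, global bivariate Moran's I
#' (attractiveness vs cases) and the number of zones with a significant
#' local bivariate statistic. Zones absent from a week's attractiveness get
#' share 0 (no visits is an observation); zones missing from the case table
#' are excluded for that week (weights re-standardized) and logged. Weeks in
#' which either variable is constant get NA statistics rather than an error.
#'
#' @param attr_weekly long tibble `week_start`, `zone_id`, `share`.
#' @param cases case tibble `zone_id`, `week_start`, `cases`.
#' @param weights [queen_weights()] on the full zone universe.
#' @param n_perm permutations per statistic (default 199 across many weeks).
#' @param seed integer; each week uses a seed derived from it.
#' @param alpha significance level for local statistics.
#' @return a tibble `week_start`, `n_zones`, `pearson_r`, `moran_cases`,
#'   `moran_cases_p`, `bivar_moran`, `bivar_moran_p`, `n_sig_local`.
#' @export
weekly_correlation_suite <- function(attr_weekly, cases, weights,
                                     n_perm = 199, seed = 1L, alpha = 0.05) {
  weeks <- sort(intersect(unique(as.Date(attr_weekly$week_start)),
                          unique(as.Date(cases$week_start))))
  weeks <- as.Date(weeks, origin = "1970-01-01")
  if (!length(weeks)) stop_mobflow("no overlapping weeks between sources")
  rows <- vector("list", length(weeks))
  for (k in seq_along(weeks)) {
    wkc <- cases[as.Date(cases$week_start) == weeks[k], ]
    have_cases <- weights$zone_ids %in% wkc$zone_id
    w <- if (all(have_cases)) weights else {
      message(sum(!have_cases), " zone(s) missing cases in week ",
              format(weeks[k]), "; excluded")
      subset_weights(weights, weights$zone_ids[have_cases])
    }
    ids <- w$zone_ids
    cs <- wkc$cases[match(ids, wkc$zone_id)]
    wka <- attr_weekly[as.Date(attr_weekly$week_start) == weeks[k], ]
    a <- rep(0, length(ids))
    hit <- match(wka$zone_id, ids)
    a[hit[!is.na(hit)]] <- wka$share[!is.na(hit)]
    r <- suite_row(a, cs, w, n_perm, seed + 13L * k, alpha)
    rows[[k]] <- tibble::tibble(week_start = weeks[k],
                                n_zones = length(ids), !!!r)
  }
  dplyr::bind_rows(rows)
}

#' Period-level correlation of attractiveness change and accumulated cases
#'
#' The period-scale variant of the weekly suite: for each named window,
#' correlates the change in attractiveness share (current period vs its
#' baseline) with the cases accumulated over the window's weeks, using the
#' same four measures.
#'
#' @param diffs tibble `period`, `zone_id`, `diff` (e.g. from
#'   [attractiveness_diff()] per period).
#' @param cases case tibble covering the windows.
#' @param weights [queen_weights()] on the zone universe.
#' @param periods named list of `c(start, end)` date pairs.
#' @inheritParams weekly_correlation_suite
#' @return a tibble `period`, `n_zones`, and the four measures.
#' @export
period_correlation_suite <- function(diffs, cases, weights, periods,
                                     n_perm = 999, seed = 1L, alpha = 0.05) {
  rows <- vector("list", length(periods))
  for (k in seq_along(names(periods))) {
    nm <- names(periods)[k]
    rng <- as.Date(periods[[nm]])
    sel <- cases[as.Date(cases$week_start) >= rng[1] &
                   as.Date(cases$week_start) <= rng[2], ]
    if (!nrow(sel)) next
    acc <- tapply(sel$cases, sel$zone_id, sum)
    ids <- weights$zone_ids
    have <- ids %in% names(acc)
    w <- if (all(have)) weights else subset_weights(weights, ids[have])
    ids <- w$zone_ids
    cs <- as.numeric(acc[ids])
    pd <- diffs[diffs$period == nm, ]
    a <- rep(0, length(ids))
    hit <- match(pd$zone_id, ids)
    a[hit[!is.na(hit)]] <- pd$diff[!is.na(hit)]
    r <- suite_row(a, cs, w, n_perm, seed + 7L * k, alpha)
    rows[[k]] <- tibble::tibble(period = nm, n_zones = length(ids), !!!r)
  }
  dplyr::bind_rows(rows)
}
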