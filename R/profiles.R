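#' Inclusive index of Monday-start analysis weeks
#'
#' @param start_monday,end_monday Monday dates bounding the analysis window
#'   (inclusive); non-Mondays are an error.
#' @return a `Date` vector of consecutive Mondays.
#' @examples
#' length(week_index("2019-01-07", "2021-02-22")) # 112 analysis weeks
#' @export
week_index <- function(start_monday, end_monday) {
  start_monday <- as.Date(start_monday)
  end_monday <- as.Date(end_monday)
  if (!is_monday(start_monday) || !is_monday(end_monday)) {
    stop_mobflow("week_index endpoints must be Mondays")
  }
  if (start_monday > end_monday) stop_mobflow("start must not be after end")
  seq(start_monday, end_monday, by = "7 days")
}

#' Per-zone temporal attractiveness profiles
#'
#' Formats weekly attractiveness shares as fixed-length vectors over the
#' analysis weeks, one per zone ever observed; weeks in which a zone drew no
#' trips are 0.
#'
#' @param attr_weekly long tibble `week_start`, `zone_id`, `share` (e.g.
#'   from [attractiveness_series()]).
#' @param weeks the analysis [week_index()].
#' @return a numeric matrix, zones (sorted ids) x weeks, with the week index
#'   attached as attribute `weeks`.
#' @export
build_profiles <- function(attr_weekly, weeks) {
  wk <- as.Date(attr_weekly$week_start)
  if (!all(wk %in% weeks)) {
    stop_mobflow("attractiveness weeks fall outside the week index")
  }
  ids <- sort(unique(attr_weekly$zone_id))
  m <- matrix(0, length(ids), length(weeks),
              dimnames = list(ids, format(weeks)))
  m[cbind(match(attr_weekly$zone_id, ids), match(wk, weeks))] <- attr_weekly$share
  attr(m, "weeks") <- weeks
  m
}

#' Cluster zones by the shape of their attractiveness profiles
#'
#' Agglomerative (bottom-up hierarchical) clustering of temporal profiles
#' under correlation distance `d = 1 - Pearson r`, so zones are grouped by
#' the shape of their trend, not its scale. Zones with zero-variance
#' profiles have no defined correlation and are dropped (and reported).
#' Rows are processed in sorted zone-id order, making merge order and
#' labels deterministic.
#'
#' @param profiles matrix from [build_profiles()].
#' @param k number of clusters (default 3).
#' @param linkage hclust linkage: `"average"` (default), `"complete"` or
#'   `"single"`.
#' @return a `profile_clustering`: list with `labels` (tibble `zone_id`,
#'   `cluster` in 1..k), `dropped` (zero-variance zone ids), `k`, `linkage`
#'   and `hclust` (the dendrogram object, heights exposed for k selection).
#' @export
cluster_profiles <- function(profiles, k = 3,
                             linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  v <- apply(profiles, 1, stats::var)
  dropped <- rownames(profiles)[v == 0]
  x <- profiles[v > 0, , drop = FALSE]
  if (nrow(x) < k) {
    stop_mobflow("fewer than k = ", k, " profiles with nonzero variance")
  }
  d <- stats::as.dist(1 - stats::cor(t(x)))
  hc <- stats::hclust(d, method = linkage)
  labels <- stats::cutree(hc, k = k)
  structure(
    list(
      labels = tibble::tibble(zone_id = names(labels),
                              cluster = as.integer(labels)),
      dropped = dropped, k = k, linkage = linkage, hclust = hc
    ),
    class = "profile_clustering"
  )
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat("<profile_clustering> k = ", x$k, " (", x$linkage,
      " linkage, correlation distance); sizes: ",
      paste(table(x$labels$cluster), collapse = ", "), sep = "")
  if (length(x$dropped)) {
    cat("; ", length(x$dropped), " zero-variance zone(s) dropped", sep = "")
  }
  cat("\n")
  invisible(x)
}
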