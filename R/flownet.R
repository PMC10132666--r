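#' Assign trip endpoints to zones
#'
#' Point-in-polygon assignment of each trip's origin and destination place
#' centroid to the zone containing it. Trips with an endpoint outside every
#' zone are dropped and counted.
#'
#' @param trips a trip tibble from [extract_daily_trips()].
#' @param zones a [zone_system()].
#' @return the trip tibble with `origin_zone` and `dest_zone` columns, only
#'   fully assigned trips retained; attribute `n_dropped` counts removals.
#' @export
assign_zones <- function(trips, zones) {
  if (!n_zones(zones)) stop_mobflow("empty zone system")
  oz <- locate_zones(trips$origin_lat, trips$origin_lon, zones)
  dz <- locate_zones(trips$dest_lat, trips$dest_lon, zones)
  keep <- !is.na(oz) & !is.na(dz)
  out <- trips[keep, ]
  out$origin_zone <- oz[keep]
  out$dest_zone <- dz[keep]
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " trip(s) dropped with endpoints outside the zone system")
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Aggregate zone-assigned trips into weekly OD matrices
#'
#' Weeks are Monday-start and dated by trip date; intra-zone trips are
#' retained as self-loops. The result is a long OD table covering all weeks.
#'
#' @param trips a zone-assigned trip tibble from [assign_zones()].
#' @return a tibble `week_start`, `origin_zone`, `dest_zone`, `trips`.
#' @export
build_weekly_od <- function(trips) {
  if (!nrow(trips)) {
    return(tibble::tibble(week_start = as.Date(character()),
                          origin_zone = character(), dest_zone = character(),
                          trips = integer()))
  }
  dt <- data.table::data.table(
    week_start = week_start(trips$date),
    origin_zone = trips$origin_zone,
    dest_zone = trips$dest_zone
  )
  od <- dt[, list(trips = .N), by = c("week_start", "origin_zone", "dest_zone")]
  data.table::setorder(od, week_start, origin_zone, dest_zone)
  tibble::as_tibble(od)
}

#' Aggregate weekly OD entries into named periods
#'
#' Sums the member weekly OD matrices of each named date range (e.g. the
#' three epidemic windows used for period-level comparison).
#'
#' @param od a weekly OD tibble from [build_weekly_od()].
#' @param periods named list of `c(start, end)` date pairs (inclusive;
#'   matched against `week_start`).
#' @return a tibble `period`, `origin_zone`, `dest_zone`, `trips`.
#' @export
aggregate_periods <- function(od, periods) {
  out <- lapply(names(periods), function(nm) {
    rng <- as.Date(periods[[nm]])
    sel <- od[od$week_start >= rng[1] & od$week_start <= rng[2], ]
    if (!nrow(sel)) return(NULL)
    dt <- data.table::as.data.table(sel)
    trips <- NULL
    agg <- dt[, list(trips = sum(trips)), by = c("origin_zone", "dest_zone")]
    data.table::setorder(agg, origin_zone, dest_zone)
    tibble::as_tibble(
      tibble::add_column(agg, period = nm, .before = "origin_zone")
    )
  })
  dplyr::bind_rows(out)
}

#' Build a directed weighted flow network for one period
#'
#' Nodes are zones with at least one incident trip (self-loops count); edge
#' weights are trip counts.
#'
#' @param od OD entries for a single period: tibble with `origin_zone`,
#'   `dest_zone`, `trips` (extra columns ignored).
#' @param period optional period label; defaults to the OD table's single
#'   `week_start`/`period` value when present.
#' @return a `flow_network`: list with `edges` (tibble), `nodes` (sorted
#'   zone ids) and `period`.
#' @export
flow_network <- function(od, period = NULL) {
  if (!nrow(od)) stop_mobflow("cannot build a flow network from an empty OD table")
  if (is.null(period)) {
    lab <- if ("week_start" %in% names(od)) unique(as.character(od$week_start))
           else if ("period" %in% names(od)) unique(od$period)
           else "all"
    if (length(lab) != 1) {
      stop_mobflow("OD table spans several periods; filter or pass `period`")
    }
    period <- lab
  }
  edges <- tibble::tibble(
    origin_zone = od$origin_zone, dest_zone = od$dest_zone,
    trips = as.integer(od$trips)
  )
  if (any(edges$trips <= 0)) stop_mobflow("edge weights must be positive counts")
  structure(
    list(edges = edges,
         nodes = sort(unique(c(edges$origin_zone, edges$dest_zone))),
         period = period),
    class = "flow_network"
  )
}

#' @export
print.flow_network <- function(x, ...) {
  s <- network_summary(x)
  cat("<flow_network> period ", x$period, ": ", s$n_nodes, " zones, ",
      s$n_edges, " directed inter-zone edges, ",
      sum(x$edges$trips), " trips (",
      sprintf("%.1f%%", 100 * s$intra_zone_trip_share), " intra-zone)\n",
      sep = "")
  invisible(x)
}

#' Zone attractiveness: share of a period's trips incident to each zone
#'
#' The weighted degree of a zone divided by the period's total trip count.
#' The default `"in"` direction (arrivals, self-loops included) reads
#' attractiveness as the share of visits a zone draws; shares sum to one
#' over the network's nodes.
#'
#' @param net a [flow_network()].
#' @param direction `"in"` (arrivals), `"out"` (departures) or `"total"`
#'   (both endpoints, halved so shares still sum to one).
#' @return a tibble `zone_id`, `share`, with the period label as attribute
#'   `period`.
#' @export
attractiveness <- function(net, direction = c("in", "out", "total")) {
  direction <- match.arg(direction)
  total <- sum(net$edges$trips)
  if (total <= 0) stop_mobflow("empty network")
  deg_in <- tapply(net$edges$trips, net$edges$dest_zone, sum)
  deg_out <- tapply(net$edges$trips, net$edges$origin_zone, sum)
  deg <- stats::setNames(rep(0, length(net$nodes)), net$nodes)
  if (direction %in% c("in", "total")) {
    deg[names(deg_in)] <- deg[names(deg_in)] + deg_in
  }
  if (direction %in% c("out", "total")) {
    deg[names(deg_out)] <- deg[names(deg_out)] + deg_out
  }
  denom <- if (direction == "total") 2 * total else total
  out <- tibble::tibble(zone_id = net$nodes,
                        share = as.numeric(deg[net$nodes]) / denom)
  attr(out, "period") <- net$period
  out
}

#' Weekly attractiveness series from a weekly OD table
#'
#' Convenience wrapper computing [attractiveness()] for every week of a
#' [build_weekly_od()] table.
#'
#' @param od weekly OD tibble.
#' @param direction see [attractiveness()].
#' @return a long tibble `week_start`, `zone_id`, `share`.
#' @export
attractiveness_series <- function(od, direction = "in") {
  weeks <- sort(unique(od$week_start))
  out <- lapply(weeks, function(w) {
    a <- attractiveness(flow_network(od[od$week_start == w, ]), direction)
    tibble::add_column(a, week_start = w, .before = "zone_id")
  })
  dplyr::bind_rows(out)
}

#' Change in attractiveness between two periods
#'
#' Difference of normalized attractiveness shares, current minus baseline,
#' over the union of the two zone universes (absent zones count as share 0).
#' Because both inputs sum to one, the differences sum to zero.
#'
#' @param curr,base attractiveness tibbles from [attractiveness()].
#' @return a tibble `zone_id`, `diff`.
#' @export
attractiveness_diff <- function(curr, base) {
  if (!nrow(curr) && !nrow(base)) stop_mobflow("both periods are empty")
  ids <- sort(union(curr$zone_id, base$zone_id))
  a1 <- stats::setNames(rep(0, length(ids)), ids)
  a0 <- a1
  a1[curr$zone_id] <- curr$share
  a0[base$zone_id] <- base$share
  tibble::tibble(zone_id = ids, diff = as.numeric(a1 - a0))
}

#' Summary counts of a flow network
#'
#' @param net a [flow_network()].
#' @return a one-row tibble: `n_nodes`, `n_edges` (distinct directed
#'   inter-zone pairs, self-loops excluded), `intra_zone_trip_share`
#'   (self-loop trips over total trips).
#' @export
network_summary <- function(net) {
  loops <- net$edges$origin_zone == net$edges$dest_zone
  tibble::tibble(
    n_nodes = length(net$nodes),
    n_edges = sum(!loops),
    intra_zone_trip_share = sum(net$edges$trips[loops]) / sum(net$edges$trips)
  )
}

#' Detect travel communities by modularity maximization
#'
#' Greedy (agglomerative) modularity maximization on the symmetrized
#' weighted graph: flows in the two directions between a zone pair are
#' summed, self-loops are kept for the modularity computation. Unusually
#' small communities — size below `mean size - 1 SD` of community sizes
#' (floored at 1) — are flagged as isolated: areas weakly connected to the
#' rest of the city.
#'
#' @param net a [flow_network()] with at least one edge.
#' @param size_threshold optional explicit minimum community size overriding
#'   the mean-minus-SD rule.
#' @return a `community_partition`: list with `membership` (tibble
#'   `zone_id`, `community`, `isolated`), `modularity` (Q of the partition)
#'   and `period`.
#' @export
detect_communities <- function(net, size_threshold = NULL) {
  e <- net$edges
  if (!nrow(e)) stop_mobflow("cannot detect communities in an edgeless network")
  a <- pmin(e$origin_zone, e$dest_zone)
  b <- pmax(e$origin_zone, e$dest_zone)
  und <- data.table::data.table(a = a, b = b, w = e$trips)
  w <- NULL
  und <- und[, list(w = sum(w)), by = c("a", "b")]
  data.table::setorder(und, a, b)
  g <- igraph::graph_from_data_frame(
    data.frame(from = und$a, to = und$b, weight = und$w),
    directed = FALSE, vertices = net$nodes
  )
  g_noloop <- igraph::delete_edges(g, which(igraph::which_loop(g)))
  cl <- igraph::cluster_fast_greedy(g_noloop,
                                    weights = igraph::E(g_noloop)$weight)
  memb <- igraph::membership(cl)
  q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
  sizes <- as.integer(table(memb))
  thr <- size_threshold %||% {
    s <- stats::sd(sizes)
    if (is.na(s)) s <- 0
    max(1, mean(sizes) - s)
  }
  isolated_comm <- as.integer(names(table(memb)))[sizes < thr]
  structure(
    list(
      membership = tibble::tibble(
        zone_id = names(memb),
        community = as.integer(memb),
        isolated = as.integer(memb) %in% isolated_comm
      ),
      modularity = q,
      period = net$period
    ),
    class = "community_partition"
  )
}

#' @export
print.community_partition <- function(x, ...) {
  k <- length(unique(x$membership$community))
  cat("<community_partition> period ", x$period, ": ", k, " communities, Q = ",
      sprintf("%.4f", x$modularity), ", ",
      sum(x$membership$isolated), " zone(s) in isolated communities\n",
      sep = "")
  invisible(x)
}

#' Optional centrality pass-throughs
#'
#' Eigenvector and betweenness centrality of a flow network, as thin
#' wrappers over igraph for exploratory use; the attractiveness analysis in
#' this package is degree-based.
#'
#' @param net a [flow_network()].
#' @return a tibble `zone_id`, `eigenvector`, `betweenness`.
#' @export
centrality_extras <- function(net) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$origin_zone, to = net$edges$dest_zone,
               weight = net$edges$trips),
    directed = TRUE, vertices = net$nodes
  )
  tibble::tibble(
    zone_id = net$nodes,
    eigenvector = igraph::eigen_centrality(g, directed = FALSE)$vector[net$nodes],
    betweenness = igraph::betweenness(g, directed = TRUE)[net$nodes]
  )
}
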