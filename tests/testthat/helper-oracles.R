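# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use naive double loops / exhaustive search so they share no
# code path with the package implementations they check.

# naive double-loop global Moran's I
moran_bf <- function(x, W) {
  n <- length(x)
  zc <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) num <- num + W[i, j] * zc[i] * zc[j]
  }
  (n / sum(W)) * num / sum(zc^2)
}

zstd <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))

# naive bivariate Moran's I
bivar_moran_bf <- function(x, y, W) {
  n <- length(x)
  zx <- zstd(x)
  zy <- zstd(y)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) num <- num + W[i, j] * zx[i] * zy[j]
  }
  (n / sum(W)) * num / sum(zx^2)
}

# naive local Moran's I vector
local_moran_bf <- function(x, W) {
  z <- zstd(x)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) s <- s + W[i, j] * z[j]
    out[i] <- z[i] * s
  }
  out
}

# connected components of points linked when within radius (BFS)
components_bf <- function(lat, lon, radius_m) {
  n <- length(lat)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- haversine_m(lat[i], lon[i], lat[j], lon[j]) <= radius_m
    }
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# weighted modularity with the self-loop convention A_ii = 2 * loop weight
modularity_bf <- function(A, membership) {
  k <- rowSums(A)
  m2 <- sum(A)
  q <- 0
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(A))) {
      if (membership[i] == membership[j]) q <- q + A[i, j] - k[i] * k[j] / m2
    }
  }
  unname(q / m2)
}

# symmetric adjacency (A_ii = 2 * loop weight) from a flow_network
adjacency_from_net <- function(net) {
  ids <- net$nodes
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(net$edges))) {
    o <- net$edges$origin_zone[r]
    d <- net$edges$dest_zone[r]
    w <- net$edges$trips[r]
    if (o == d) A[o, o] <- A[o, o] + 2 * w else {
      A[o, d] <- A[o, d] + w
      A[d, o] <- A[d, o] + w
    }
  }
  A
}

# all set partitions of 1..n (Bell-number enumeration, fine for n <= 8)
set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in set_partitions(n - 1L)) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    p[[length(p) + 1L]] <- n
    out[[length(out) + 1L]] <- p
  }
  out
}

partition_to_membership <- function(p, n) {
  memb <- integer(n)
  for (b in seq_along(p)) memb[p[[b]]] <- b
  memb
}

# point-table fixture builder
make_points <- function(user_id, timestamp, lat, lon) {
  tibble::tibble(
    user_id = user_id,
    timestamp = as.POSIXct(timestamp, tz = "UTC"),
    lat = lat, lon = lon
  )
}

# move a coordinate north/east by meters (small-displacement approximation
# is avoided: exact spherical arc along a meridian / the equator)
lat_offset <- function(meters) meters / 111194.9266
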