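# Independent brute-force oracles, deliberately avoiding the package's
# distance code paths: a hand-written Dijkstra on a graph densified with
# temporary vertices at the query locations, and discretization oracles for
# m(u, t) and the circumradius.

# insert locations (data frame seg, offset) as temporary vertices; returns
# edge list (a, b, w) on n_nodes nodes and the node index of each location
densify_graph <- function(net, seg, offset) {
  nv <- nrow(net$vertices)
  n_nodes <- nv
  loc_node <- integer(length(seg))
  ea <- integer(0); eb <- integer(0); ew <- numeric(0)
  for (s in seq_len(nrow(net$edges))) {
    idx <- which(seg == s)
    ord <- idx[order(offset[idx])]
    prev <- net$edges[s, 1L]
    prev_off <- 0
    for (k in ord) {
      n_nodes <- n_nodes + 1L
      loc_node[k] <- n_nodes
      ea <- c(ea, prev); eb <- c(eb, n_nodes); ew <- c(ew, offset[k] - prev_off)
      prev <- n_nodes; prev_off <- offset[k]
    }
    ea <- c(ea, prev); eb <- c(eb, net$edges[s, 2L])
    ew <- c(ew, net$lengths[s] - prev_off)
  }
  list(n = n_nodes, a = ea, b = eb, w = ew, loc_node = loc_node)
}

# naive O(V^2) Dijkstra
dijkstra_from <- function(graph, source) {
  dist <- rep(Inf, graph$n)
  done <- rep(FALSE, graph$n)
  dist[source] <- 0
  repeat {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0L) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    out1 <- which(graph$a == u)
    out2 <- which(graph$b == u)
    nb <- c(graph$b[out1], graph$a[out2])
    wt <- c(graph$w[out1], graph$w[out2])
    relax <- dist[u] + wt < dist[nb]
    dist[nb[relax]] <- dist[u] + wt[relax]
  }
  dist
}

# oracle shortest-path distance between two locations
oracle_loc_dist <- function(net, u, v) {
  g <- densify_graph(net, c(u$seg, v$seg), c(u$offset, v$offset))
  dijkstra_from(g, g$loc_node[1L])[g$loc_node[2L]]
}

# oracle distances from one location to every original vertex
oracle_vertex_dists <- function(net, u) {
  g <- densify_graph(net, u$seg, u$offset)
  dijkstra_from(g, g$loc_node[1L])[seq_len(nrow(net$vertices))]
}

# discretization oracle for m(u, t): sample points every eps along every
# segment, flag those within eps/2 of distance t from u, and count maximal
# runs of flagged consecutive samples within each segment
oracle_m <- function(net, u, t, eps = 0.01) {
  dv <- oracle_vertex_dists(net, u)
  count <- 0L
  for (s in seq_len(nrow(net$edges))) {
    len <- net$lengths[s]
    ss <- seq(eps / 2, len - eps / 2, by = eps)
    d <- pmin(dv[net$edges[s, 1L]] + ss, dv[net$edges[s, 2L]] + (len - ss))
    if (s == u$seg[1L]) d <- pmin(d, abs(ss - u$offset[1L]))
    flag <- abs(d - t) <= eps / 2
    count <- count + sum(diff(c(FALSE, flag)) == 1L)
  }
  count
}

# discretization oracle for the circumradius: minimize, over sample points at
# the given spacing, the eccentricity computed as the largest distance to any
# leaf (on a tree the farthest point is always a leaf)
oracle_circumradius <- function(net, spacing = 0.005) {
  leaves <- which(net$degree == 1L)
  dvl <- vapply(leaves, function(l) {
    g <- densify_graph(net, integer(0), numeric(0))
    dijkstra_from(g, l)
  }, numeric(nrow(net$vertices)))
  best <- Inf
  for (s in seq_len(nrow(net$edges))) {
    len <- net$lengths[s]
    ss <- seq(0, len, by = spacing)
    a <- net$edges[s, 1L]; b <- net$edges[s, 2L]
    ecc <- rep(0, length(ss))
    for (k in seq_along(leaves)) {
      ecc <- pmax(ecc, pmin(dvl[a, k] + ss, dvl[b, k] + (len - ss)))
    }
    best <- min(best, min(ecc))
  }
  best
}

# rigid motion: random rotation (QR of a Gaussian matrix) plus translation
rigid_motion <- function(vertices) {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  sweep(vertices %*% Q, 2, stats::rnorm(3, 0, 50), `+`)
}
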