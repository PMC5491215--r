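# Geometry and topology of 3D linear networks (trees).
#
# A network is the union of straight line segments in R^3. All statistical
# machinery downstream only ever sees arc lengths and shortest-path distances,
# so the same code covers planar (z constant) networks as a special case.

#' Locations on a linear network
#'
#' A `netloc` is a set of points constrained to lie on a network, addressed as
#' (segment id, arc-length offset from the segment's first endpoint).
#'
#' @param seg integer vector of segment ids (1-based).
#' @param offset numeric vector of offsets in micrometres, recycled against
#'   `seg`.
#' @return an object of class `netloc` with fields `seg` and `offset`.
#' @seealso [build_network()], [snap_to_network()]
#' @export
netloc <- function(seg, offset) {
  seg <- as.integer(seg)
  offset <- as.numeric(offset)
  n <- max(length(seg), length(offset))
  seg <- rep_len(seg, n)
  offset <- rep_len(offset, n)
  if (anyNA(seg) || anyNA(offset)) stopf("netloc fields must not contain NA")
  structure(list(seg = seg, offset = offset), class = "netloc")
}

#' @export
length.netloc <- function(x) length(x$seg)

#' @export
`[.netloc` <- function(x, i) netloc(x$seg[i], x$offset[i])

#' @export
print.netloc <- function(x, ...) {
  cat(sprintf("<netloc: %d location(s) on a linear network>\n", length(x)))
  print(data.frame(seg = x$seg, offset = x$offset), ...)
  invisible(x)
}

#' Build a 3D linear network (tree)
#'
#' Constructs the continuum tree \eqn{L} from vertex coordinates and edges.
#' Segment arc lengths are the 3D Euclidean distances between endpoints, and
#' the total length \eqn{|L|} is their sum. Shortest-path distances between
#' vertices are precomputed (Dijkstra via \pkg{igraph}) and cached on the
#' object; every continuum distance downstream reduces to offset arithmetic
#' against this table.
#'
#' Dendritic arborisations are acyclic, so cyclic or disconnected graphs are
#' rejected rather than half-supported: on a disconnected network some
#' shortest-path distances would be infinite.
#'
#' @param vertices numeric matrix (or data frame) with columns x, y, z in
#'   micrometres, one row per vertex.
#' @param edges two-column integer matrix of vertex index pairs (1-based).
#' @param root vertex index to use as the tree root (distance-to-root
#'   covariate origin); default 1.
#' @return an object of class `linnet3d` with fields `vertices`, `edges`,
#'   `lengths`, `total_length`, `root` (vertex index), `root_loc` (a
#'   [netloc()]), and the cached vertex distance matrix `vdist`.
#' @examples
#' v <- rbind(c(0, 0, 0), c(0, 0, 4), c(3, 0, 4), c(0, 3, 4))
#' net <- build_network(v, rbind(c(1, 2), c(2, 3), c(2, 4)))
#' net$total_length # 10
#' @export
build_network <- function(vertices, edges, root = 1L) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3L) stopf("vertices must have 3 columns (x, y, z)")
  storage.mode(vertices) <- "double"
  if (!all(is.finite(vertices))) stopf("vertex coordinates must be finite")
  edges <- matrix(as.integer(as.matrix(edges)), ncol = 2L)
  nv <- nrow(vertices)
  ne <- nrow(edges)
  if (ne < 1L) stopf("network needs at least one segment")
  if (any(edges < 1L) || any(edges > nv)) stopf("edge refers to a vertex index out of range")
  if (any(edges[, 1L] == edges[, 2L])) stopf("edge endpoints must be distinct vertices")
  d3 <- vertices[edges[, 1L], , drop = FALSE] - vertices[edges[, 2L], , drop = FALSE]
  lengths <- sqrt(rowSums(d3^2))
  if (any(lengths <= 0)) {
    stopf("zero-length segment(s): %s", paste(which(lengths <= 0), collapse = ", "))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < nv) g <- igraph::add_vertices(g, nv - igraph::vcount(g))
  if (!igraph::is_connected(g)) {
    stopf("network graph is disconnected; all locations must be joined by a path")
  }
  if (ne != nv - 1L) {
    stopf("network graph contains a cycle (%d edges for %d vertices); only trees are supported",
          ne, nv)
  }
  root <- as.integer(root)
  if (length(root) != 1L || root < 1L || root > nv) stopf("root vertex index out of range")
  vdist <- igraph::distances(g, weights = lengths, algorithm = "dijkstra")
  dimnames(vdist) <- NULL
  deg <- tabulate(edges, nbins = nv)
  # canonical representation of each vertex: lowest incident segment id
  f1 <- match(seq_len(nv), edges[, 1L])
  f2 <- match(seq_len(nv), edges[, 2L])
  first_seg <- pmin(f1, f2, na.rm = TRUE)
  at_start <- !is.na(f1) & (is.na(f2) | f1 <= f2)
  net <- structure(
    list(
      vertices = vertices,
      edges = edges,
      lengths = lengths,
      total_length = sum(lengths),
      root = root,
      root_loc = netloc(first_seg[root],
                        if (at_start[root]) 0 else lengths[first_seg[root]]),
      vdist = vdist,
      degree = deg,
      first_seg = first_seg,
      vertex_at_start = at_start
    ),
    class = "linnet3d"
  )
  net
}

#' @export
print.linnet3d <- function(x, ...) {
  cat(sprintf(
    "<linnet3d: tree with %d vertices, %d segments, |L| = %.2f um, R = %.2f um>\n",
    nrow(x$vertices), nrow(x$edges), x$total_length, circumradius(x)))
  invisible(x)
}

# --- location validation / canonicalisation -------------------------------

# snap offsets within tol of a vertex onto the vertex and re-express vertex
# locations by their canonical (lowest incident segment) representation, so
# that locations coinciding with a shared vertex compare equal.
canonical_locs <- function(net, loc, tol = 1e-9) {
  seg <- loc$seg
  offset <- loc$offset
  if (length(seg) == 0L) return(loc)
  if (any(seg < 1L) || any(seg > nrow(net$edges))) stopf("segment id off the network")
  len <- net$lengths[seg]
  bad <- offset < -tol | offset > len + tol
  if (any(bad)) {
    stopf("offset out of range on segment(s) %s",
          paste(unique(seg[bad]), collapse = ", "))
  }
  offset <- pmin(pmax(offset, 0), len)
  at0 <- offset <= tol
  at1 <- offset >= len - tol
  vert <- integer(length(seg))
  vert[at0] <- net$edges[seg[at0], 1L]
  vert[at1 & !at0] <- net$edges[seg[at1 & !at0], 2L]
  isv <- at0 | at1
  if (any(isv)) {
    v <- vert[isv]
    seg[isv] <- net$first_seg[v]
    offset[isv] <- ifelse(net$vertex_at_start[v], 0, net$lengths[net$first_seg[v]])
  }
  netloc(seg, offset)
}

# distances from each location to every vertex; rows = locations
loc_vertex_dists <- function(net, loc) {
  a <- net$edges[loc$seg, 1L]
  b <- net$edges[loc$seg, 2L]
  len <- net$lengths[loc$seg]
  pmin(loc$offset + net$vdist[a, , drop = FALSE],
       (len - loc$offset) + net$vdist[b, , drop = FALSE])
}

#' Shortest-path distance between network locations
#'
#' The distance \eqn{d_L(u, v)} is the minimum arc length over paths along the
#' network. On a tree the path is unique: two locations on the same segment
#' are separated by their offset difference, otherwise the path runs through
#' segment endpoints and the cached vertex distance table.
#'
#' @param net a `linnet3d`.
#' @param u,v [netloc()] objects; recycled to a common length, distances are
#'   computed elementwise.
#' @return numeric vector of distances in micrometres (symmetric in `u`, `v`).
#' @export
shortest_path_distance <- function(net, u, v) {
  u <- canonical_locs(net, u)
  v <- canonical_locs(net, v)
  n <- max(length(u), length(v))
  u <- u[rep_len(seq_len(length(u)), n)]
  v <- v[rep_len(seq_len(length(v)), n)]
  a <- net$edges[u$seg, 1L]; b <- net$edges[u$seg, 2L]
  cc <- net$edges[v$seg, 1L]; dd <- net$edges[v$seg, 2L]
  lu <- net$lengths[u$seg]; lv <- net$lengths[v$seg]
  da <- u$offset; db <- lu - u$offset
  dc <- v$offset; dv <- lv - v$offset
  d <- pmin(da + net$vdist[cbind(a, cc)] + dc,
            da + net$vdist[cbind(a, dd)] + dv,
            db + net$vdist[cbind(b, cc)] + dc,
            db + net$vdist[cbind(b, dd)] + dv)
  same <- u$seg == v$seg
  d[same] <- abs(u$offset[same] - v$offset[same])
  d
}

#' All pairwise shortest-path distances between locations
#'
#' @param net a `linnet3d`.
#' @param loc a [netloc()] of n locations.
#' @return symmetric n x n matrix of shortest-path distances (um).
#' @export
pair_distances <- function(net, loc) {
  loc <- canonical_locs(net, loc)
  n <- length(loc)
  if (n == 0L) return(matrix(numeric(0), 0L, 0L))
  a <- net$edges[loc$seg, 1L]
  b <- net$edges[loc$seg, 2L]
  len <- net$lengths[loc$seg]
  da <- loc$offset
  db <- len - loc$offset
  D <- net$vdist
  M <- pmin(outer(da, da, `+`) + D[a, a, drop = FALSE],
            outer(da, db, `+`) + D[a, b, drop = FALSE],
            outer(db, da, `+`) + D[b, a, drop = FALSE],
            outer(db, db, `+`) + D[b, b, drop = FALSE])
  same <- outer(loc$seg, loc$seg, `==`)
  M[same] <- abs(outer(loc$offset, loc$offset, `-`))[same]
  diag(M) <- 0
  M
}

#' Distance to the tree root
#'
#' The covariate \eqn{d(u) = d_L(u, r)} used throughout the intensity
#' analysis: the shortest-path distance from each location to the stored root
#' (the soma attachment in a dendritic reconstruction).
#'
#' @param net a `linnet3d` with a root set.
#' @param u a [netloc()] (vectorized).
#' @return numeric vector of distances in micrometres.
#' @export
distance_to_root <- function(net, u) {
  if (is.null(net$root)) stopf("network has no root set")
  u <- canonical_locs(net, u)
  a <- net$edges[u$seg, 1L]
  b <- net$edges[u$seg, 2L]
  len <- net$lengths[u$seg]
  dr <- net$vdist[, net$root]
  pmin(u$offset + dr[a], (len - u$offset) + dr[b])
}

# distance profile of the network as seen from a single location u:
# every edge (split at u if u is interior) is monotone in distance on a tree,
# so the profile is a list of [enter, exit) ramps plus exact vertex distances.
distance_profile <- function(net, u, tol = 1e-9) {
  u <- canonical_locs(net, u[1L])
  a <- net$edges[u$seg, 1L]
  b <- net$edges[u$seg, 2L]
  len <- net$lengths[u$seg]
  dv <- pmin(u$offset + net$vdist[a, ], (len - u$offset) + net$vdist[b, ])
  p <- net$edges[, 1L]
  q <- net$edges[, 2L]
  enter <- pmin(dv[p], dv[q])
  exit <- enter + net$lengths
  interior <- u$offset > tol && u$offset < len - tol
  if (interior) {
    # replace the host segment by its two half-edges radiating from u
    enter[u$seg] <- 0
    exit[u$seg] <- u$offset
    enter <- c(enter, 0)
    exit <- c(exit, len - u$offset)
    dv <- c(dv, 0) # u itself as a pseudo-vertex at distance 0
  }
  list(enter = enter, exit = exit, vdist = dv, ecc = max(dv))
}

#' Exact-distance count m(u, t)
#'
#' Counts the network points lying at exact shortest-path distance `t` from
#' `u`: \eqn{m(u,t) = \#\{v \in L : d_L(u,v) = t\}}. This is the geometric
#' correction weight of the corrected network K function. On a tree,
#' \eqn{m(u,0) = 1} and, for \eqn{t > 0}, the count is one per edge whose open
#' interval of distances from `u` contains `t`, plus one per vertex at exactly
#' distance `t` (a vertex counts once regardless of its degree).
#'
#' @param net a `linnet3d`.
#' @param u a single-location [netloc()].
#' @param t numeric vector of nonnegative distances (um).
#' @return integer vector, one count per element of `t`.
#' @examples
#' v <- rbind(c(0, 0, 0), c(10, 0, 0))
#' net <- build_network(v, cbind(1, 2))
#' count_at_distance(net, netloc(1, 3), c(0, 2, 7, 8)) # 1 2 1 0
#' @export
count_at_distance <- function(net, u, t) {
  if (any(t < 0)) stopf("distance t must be nonnegative")
  prof <- distance_profile(net, u)
  tol <- 1e-8 * max(1, prof$ecc)
  se <- sort(prof$enter)
  sx <- sort(prof$exit)
  sv <- sort(prof$vdist)
  inside <- findInterval(t - tol, se) - findInterval(t + tol, sx)
  atv <- findInterval(t + tol, sv) - findInterval(t - tol, sv)
  as.integer(inside + atv)
}

# largest shortest-path distance from u to any point of the network
eccentricity <- function(net, u) distance_profile(net, u)$ecc

#' Circumradius of a network
#'
#' The radius \eqn{R} of the smallest shortest-path disc containing the whole
#' network, \eqn{R = \sup\{t : m(u,t) > 0 \ \forall u \in L\}}; the corrected
#' K functions are defined for distances up to \eqn{R}. On a geodesic tree
#' this equals half the continuum diameter, whose endpoints are vertices, so
#' it is computed exactly from the cached vertex distance table.
#'
#' @param net a `linnet3d`.
#' @return circumradius in micrometres.
#' @export
circumradius <- function(net) max(net$vdist) / 2

#' Snap 3D points onto a network
#'
#' Maps free 3D coordinates (for example reconstructed spine attachment
#' points) to the nearest location on the network's segments by orthogonal
#' projection; ties are broken by lowest segment id, then lowest offset.
#'
#' @param net a `linnet3d`.
#' @param p numeric matrix (n x 3) or length-3 vector of coordinates (um).
#' @param max_dist maximum allowed Euclidean residual (um); a point farther
#'   than this from every segment raises an error naming the point.
#' @return a [netloc()] of snapped locations, with the Euclidean residuals in
#'   attribute `residual`.
#' @export
snap_to_network <- function(net, p, max_dist = 5) {
  if (max_dist <= 0) stopf("max_dist must be positive")
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  p <- as.matrix(p)
  if (ncol(p) != 3L) stopf("points must have 3 columns (x, y, z)")
  A <- net$vertices[net$edges[, 1L], , drop = FALSE]
  B <- net$vertices[net$edges[, 2L], , drop = FALSE]
  AB <- B - A
  len2 <- rowSums(AB^2)
  n <- nrow(p)
  seg <- integer(n)
  off <- numeric(n)
  res <- numeric(n)
  for (i in seq_len(n)) {
    AP <- sweep(A, 2L, p[i, ], `-`)
    tt <- pmin(pmax(-rowSums(AP * AB) / len2, 0), 1)
    proj2 <- rowSums((AP + AB * tt)^2)
    d <- sqrt(proj2)
    j <- which(d <= min(d) + 1e-12)
    j <- j[order(j, tt[j])][1L] # lowest segment id, then lowest offset
    seg[i] <- j
    off[i] <- tt[j] * net$lengths[j]
    res[i] <- d[j]
  }
  bad <- res > max_dist
  if (any(bad)) {
    k <- which(bad)[1L]
    stopf("point %d at (%.3f, %.3f, %.3f) is %.3f um from the network (max_dist = %g)",
          k, p[k, 1L], p[k, 2L], p[k, 3L], res[k], max_dist)
  }
  out <- netloc(seg, off)
  attr(out, "residual") <- res
  out
}
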