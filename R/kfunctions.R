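# Network K functions: empirical K_net, geometrically corrected K_L, and
# inhomogeneous K_LI. All are cumulative sums of nonnegative pair weights
# evaluated exactly at the grid distances.

#' Distance grid for summary functions
#'
#' @param net a `linnet3d`.
#' @param n number of grid values.
#' @param r_max largest distance; defaults to 0.98 times the circumradius,
#'   2\% below the validity bound of the corrected K functions.
#' @return class `distance_grid`: list with `values` (equispaced from 0) and
#'   `r_max`.
#' @export
distance_grid <- function(net, n = 512L, r_max = NULL) {
  if (is.null(r_max)) r_max <- 0.98 * circumradius(net)
  if (r_max <= 0) stopf("r_max must be positive")
  structure(list(values = seq(0, r_max, length.out = n), r_max = r_max),
            class = "distance_grid")
}

as_grid_values <- function(grid, net) {
  if (inherits(grid, "distance_grid")) return(grid$values)
  if (is.null(grid)) return(distance_grid(net)$values)
  v <- as.numeric(grid)
  if (any(diff(v) <= 0) || any(v < 0)) stopf("grid values must be nonnegative and strictly increasing")
  v
}

new_sumfun <- function(grid, values, kind) {
  out <- data.frame(d = grid, value = values, theoretical = grid)
  attr(out, "kind") <- kind
  class(out) <- c("netsumfun", "data.frame")
  out
}

#' @export
print.netsumfun <- function(x, ...) {
  cat(sprintf("<netsumfun %s: %d grid points on [0, %.2f] um>\n",
              attr(x, "kind"), nrow(x), max(x$d)))
  invisible(x)
}

#' @export
plot.netsumfun <- function(x, ...,
                           xlab = "d (um)", ylab = attr(x, "kind"),
                           col = "black") {
  graphics::plot(x$d, x$value, type = "l", xlab = xlab, ylab = ylab, col = col, ...)
  graphics::lines(x$d, x$theoretical, lty = 2, col = "red")
  invisible(x)
}

# step-function evaluation: sum of weights of pairs with distance <= each grid d
cumulate_pairs <- function(dists, weights, grid) {
  ord <- order(dists)
  cw <- c(0, cumsum(weights[ord]))
  cw[findInterval(grid, dists[ord]) + 1L]
}

# per ordered pair (i, j != i): the inter-event distance and the geometric
# correction m(x_i, d_ij). Returns n*(n-1) vectors (i-major order).
pair_dist_m <- function(pattern) {
  net <- pattern$net
  loc <- canonical_locs(net, pattern$loc)
  n <- length(loc)
  D <- pair_distances(net, loc)
  dist <- numeric(n * (n - 1L))
  mval <- integer(n * (n - 1L))
  pos <- 0L
  for (i in seq_len(n)) {
    ti <- D[i, -i]
    prof <- distance_profile(net, loc[i])
    tol <- 1e-8 * max(1, prof$ecc)
    se <- sort(prof$enter); sx <- sort(prof$exit); sv <- sort(prof$vdist)
    mi <- findInterval(ti - tol, se) - findInterval(ti + tol, sx) +
      findInterval(ti + tol, sv) - findInterval(ti - tol, sv)
    if (any(mi <= 0)) {
      stopf("internal error: m(u,t) = 0 at an inter-event distance (t beyond eccentricity?)")
    }
    idx <- pos + seq_len(n - 1L)
    dist[idx] <- ti
    mval[idx] <- mi
    pos <- pos + n - 1L
  }
  list(dist = dist, m = mval, n = n)
}

#' Empirical network K function
#'
#' The network analogue of Ripley's K with shortest-path distances:
#' \deqn{\hat K_{net}(d) = \frac{|L|}{n(n-1)} \sum_i \sum_{j \ne i}
#'   1\{d_L(x_i, x_j) \le d\}.}
#' Its value depends on the geometry of the network, so curves from different
#' networks are not directly comparable; see [k_corrected()].
#'
#' @param pattern a `netppp` with at least two events.
#' @param grid a [distance_grid()], a numeric vector of distances, or `NULL`
#'   for the default grid.
#' @return a `netsumfun` data frame with columns `d`, `value`, `theoretical`.
#' @export
k_net <- function(pattern, grid = NULL) {
  if (pattern$n < 2L) stopf("network K function needs at least two events")
  g <- as_grid_values(grid, pattern$net)
  D <- pair_distances(pattern$net, pattern$loc)
  dists <- D[row(D) != col(D)]
  pref <- pattern$net$total_length / (pattern$n * (pattern$n - 1L))
  new_sumfun(g, pref * cumulate_pairs(dists, rep.int(1, length(dists)), g), "Knet")
}

#' Geometrically corrected network K function
#'
#' Each ordered pair is down-weighted by the exact-distance count at its
#' separation:
#' \deqn{\hat K_L(d) = \frac{|L|}{n(n-1)} \sum_i \sum_{j \ne i}
#'   \frac{1\{d_L(x_i, x_j) \le d\}}{m(x_i, d_L(x_i, x_j))},}
#' valid for \eqn{0 \le d \le R} (the circumradius). Under a homogeneous
#' Poisson process \eqn{K_L(d) = d}, which makes corrected curves comparable
#' across networks of different geometry.
#'
#' @inheritParams k_net
#' @return a `netsumfun`; `theoretical` holds the Poisson reference `d`.
#' @export
k_corrected <- function(pattern, grid = NULL) {
  if (pattern$n < 2L) stopf("corrected K function needs at least two events")
  g <- as_grid_values(grid, pattern$net)
  R <- circumradius(pattern$net)
  if (max(g) > R * (1 + 1e-9)) {
    stopf("grid r_max (%.3f) exceeds the circumradius R = %.3f; K_L is defined for d <= R",
          max(g), R)
  }
  pm <- pair_dist_m(pattern)
  pref <- pattern$net$total_length / (pattern$n * (pattern$n - 1L))
  new_sumfun(g, pref * cumulate_pairs(pm$dist, 1 / pm$m, g), "KL")
}

#' Inhomogeneous geometrically corrected network K function
#'
#' Extends [k_corrected()] to non-constant intensity by weighting each pair
#' with the reciprocal product of the intensities at its events:
#' \deqn{\hat K_{LI}(d) = \frac{1}{\sum_i 1/\hat\lambda(x_i)} \sum_i \sum_{j \ne i}
#'   \frac{1\{d_L(x_i,x_j) \le d\}}
#'        {\hat\lambda(x_i)\,\hat\lambda(x_j)\, m(x_i, d_L(x_i,x_j))}.}
#'
#' @inheritParams k_net
#' @param intensity intensity at the events: a numeric vector of positive
#'   values (events/um, one per event) or a fitted [log_quadratic()] model to
#'   evaluate at the events' distance to root.
#' @return a `netsumfun`; `theoretical` holds the Poisson reference `d`.
#' @export
k_inhom <- function(pattern, intensity, grid = NULL) {
  if (pattern$n < 2L) stopf("inhomogeneous K function needs at least two events")
  if (inherits(intensity, "logquad")) {
    intensity <- predict_intensity(intensity, distance_to_root(pattern$net, pattern$loc))
  }
  lam <- as.numeric(intensity)
  if (length(lam) != pattern$n) stopf("need one intensity value per event")
  if (any(!is.finite(lam)) || any(lam <= 0)) stopf("intensities must be positive and finite")
  g <- as_grid_values(grid, pattern$net)
  R <- circumradius(pattern$net)
  if (max(g) > R * (1 + 1e-9)) {
    stopf("grid r_max (%.3f) exceeds the circumradius R = %.3f; K_LI is defined for d <= R",
          max(g), R)
  }
  pm <- pair_dist_m(pattern)
  n <- pattern$n
  li <- rep(lam, each = n - 1L)
  lj <- lam[as.vector(vapply(seq_len(n), function(i) seq_len(n)[-i], integer(n - 1L)))]
  w <- 1 / (li * lj * pm$m)
  pref <- 1 / sum(1 / lam)
  new_sumfun(g, pref * cumulate_pairs(pm$dist, w, g), "KLI")
}
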