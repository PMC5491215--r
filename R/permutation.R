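# Studentized permutation inference for replicated grouped patterns: the H
# statistic integrates squared studentized differences of group mean summary
# functions, and significance comes from permuting pattern-to-group labels.

# core H computation on a matrix of summary curves (rows = grid, cols =
# patterns) with integer group labels; x is the integration grid, w its
# trapezoid weights, range the normalizing interval length d1 - d0.
h_stat_matrix <- function(curves, labels, w, range) {
  gs <- sort(unique(labels))
  g <- length(gs)
  means <- matrix(0, nrow(curves), g)
  sbar2 <- numeric(g)
  m <- integer(g)
  for (k in seq_len(g)) {
    M <- curves[, labels == gs[k], drop = FALSE]
    m[k] <- ncol(M)
    mu <- rowMeans(M)
    means[, k] <- mu
    vard <- rowSums((M - mu)^2) / (m[k] - 1L)
    sbar2[k] <- sum(w * vard) / range
  }
  H <- 0
  for (i in seq_len(g - 1L)) {
    for (j in (i + 1L):g) {
      num <- sum(w * (means[, i] - means[, j])^2)
      den <- sbar2[i] / m[i] + sbar2[j] / m[j]
      if (den == 0) {
        if (num > 0) return(Inf)
        # 0/0 pair contributes nothing
      } else {
        H <- H + num / den
      }
    }
  }
  H
}

#' Studentized H statistic for grouped summary functions
#'
#' Compares group mean summary functions over a distance interval:
#' \deqn{H = \sum_{i < j} \int_{d_0}^{d_1}
#'   \frac{(\bar T_i(d) - \bar T_j(d))^2}
#'        {\bar s_i^2/m_i + \bar s_j^2/m_j}\, dd,}
#' where \eqn{\bar T_i} is the mean curve of group \eqn{i} and \eqn{\bar s_i^2}
#' its within-group variance averaged over the interval,
#' \eqn{\bar s_i^2 = \frac{1}{d_1-d_0}\int_{d_0}^{d_1}
#'   \frac{1}{m_i-1}\sum_j (\hat T_{ij}(d) - \bar T_i(d))^2 dd.}
#' Integrals use the trapezoidal rule; a pair with zero variance contributes
#' 0 when its mean curves agree and `Inf` otherwise.
#'
#' @param summaries a list of groups, each a list of `netsumfun` objects
#'   computed on a common grid (curves are linearly interpolated onto
#'   `[d0, d1]`).
#' @param d0,d1 integration limits in micrometres; the common grid must cover
#'   the interval.
#' @return the scalar H statistic.
#' @export
h_statistic <- function(summaries, d0, d1) {
  if (length(summaries) < 2L) stopf("need at least two groups")
  m <- vapply(summaries, length, integer(1L))
  if (any(m < 1L)) stopf("every group must contain at least one summary")
  if (any(m == 1L)) stopf("group(s) %s contain a single pattern; within-group variance is undefined",
                          paste(which(m == 1L), collapse = ", "))
  if (d1 <= d0) stopf("d1 must exceed d0")
  grid <- summaries[[1L]][[1L]]$d
  if (min(grid) > d0 + 1e-9 || max(grid) < d1 - 1e-9) {
    stopf("common grid [%.3f, %.3f] does not cover [d0, d1] = [%.3f, %.3f]",
          min(grid), max(grid), d0, d1)
  }
  x <- unique(c(d0, grid[grid > d0 & grid < d1], d1))
  curves <- do.call(cbind, lapply(unlist(summaries, recursive = FALSE), function(sf) {
    stats::approx(sf$d, sf$value, xout = x)$y
  }))
  labels <- rep(seq_along(summaries), m)
  h_stat_matrix(curves, labels, trapezoid_weights(x), d1 - d0)
}

#' Studentized permutation test for replicated grouped patterns
#'
#' Tests whether groups of replicated point patterns share a common spatial
#' structure. Each pattern's summary function (geometrically corrected K by
#' default) is computed on its own network over a common distance grid --
#' this is what makes patterns on different networks comparable -- and the
#' studentized [h_statistic()] of the observed grouping is ranked among the
#' values obtained under random permutations of the pattern-to-group labels
#' (group sizes preserved): \eqn{p = (1 + \#\{H^* \ge H_{obs}\})/(1 + n_{perm})}.
#'
#' For `summary = "KLI"` each pattern's intensity is its own fitted
#' log-quadratic model.
#'
#' @param groups a `grouped_patterns` object or a list of lists of `netppp`
#'   objects; every group needs at least two patterns, and at least three are
#'   recommended for a usable within-group variance.
#' @param summary `"KL"` or `"KLI"`.
#' @param d0 lower integration limit (um).
#' @param d1 upper integration limit (um); default is 0.98 times the smallest
#'   circumradius over all networks. A `d1` beyond any network's circumradius
#'   is an error (that network's corrected K is undefined there) naming the
#'   offending patterns.
#' @param n_perm number of random permutations.
#' @param grid_size number of grid points on `[d0, d1]`.
#' @param seed optional integer seed.
#' @return class `perm_test`: list with `h_observed`, `h_permuted`,
#'   `p_value`, `n_perm`, `interval`, `sizes`, `summary`.
#' @export
studentized_permutation_test <- function(groups, summary = c("KL", "KLI"),
                                         d0 = 0, d1 = NULL,
                                         n_perm = 1000L, grid_size = 256L,
                                         seed = NULL) {
  summary <- match.arg(summary)
  if (inherits(groups, "grouped_patterns")) groups <- groups$groups
  g <- length(groups)
  if (g < 2L) stopf("need at least two groups")
  m <- vapply(groups, length, integer(1L))
  if (any(m < 2L)) stopf("every group needs at least two patterns (sizes: %s)",
                         paste(m, collapse = ", "))
  if (any(m < 3L)) warnf("group(s) with fewer than three patterns: within-group variance estimates will be imprecise")
  pats <- unlist(groups, recursive = FALSE)
  labels <- rep(seq_len(g), m)
  Rs <- vapply(pats, function(p) circumradius(p$net), numeric(1L))
  if (is.null(d1)) d1 <- 0.98 * min(Rs)
  if (d1 > min(Rs)) {
    bad <- which(Rs < d1)
    stopf("d1 = %.2f um exceeds the circumradius of pattern(s) %s (R = %s); drop them or reduce d1",
          d1, paste(bad, collapse = ", "),
          paste(sprintf("%.2f", Rs[bad]), collapse = ", "))
  }
  if (d1 <= d0) stopf("d1 must exceed d0")
  x <- seq(d0, d1, length.out = grid_size)
  curves <- vapply(pats, function(p) summary_curve(p, summary, x),
                   numeric(grid_size))
  w <- trapezoid_weights(x)
  h_obs <- h_stat_matrix(curves, labels, w, d1 - d0)
  with_seed(seed, {
    h_perm <- vapply(seq_len(n_perm), function(b) {
      h_stat_matrix(curves, sample(labels), w, d1 - d0)
    }, numeric(1L))
    p <- (1 + sum(h_perm >= h_obs)) / (1 + n_perm)
    structure(list(h_observed = h_obs, h_permuted = h_perm, p_value = p,
                   n_perm = as.integer(n_perm), interval = c(d0 = d0, d1 = d1),
                   sizes = m, summary = summary),
              class = "perm_test")
  })
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Studentized permutation test (%s, %d groups of sizes %s)\n",
              x$summary, length(x$sizes), paste(x$sizes, collapse = ", ")))
  cat(sprintf("  interval [%.2f, %.2f] um; H = %.4f; %d permutations; p-value = %.4g\n",
              x$interval[1L], x$interval[2L], x$h_observed, x$n_perm, x$p_value))
  invisible(x)
}
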