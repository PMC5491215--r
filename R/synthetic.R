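# Synthetic dendritic trees and replicated grouped patterns. The generator is
# a branching random walk calibrated to the descriptive statistics of
# reconstructed human pyramidal-cell dendrites: total length a few hundred to
# a few thousand micrometres, a handful to ~20 bifurcations, and a short
# unbranched trunk near the soma.

#' Specification of a synthetic dendrite
#'
#' @param length_range range (um) from which the target total tree length is
#'   drawn uniformly.
#' @param branch_rate bifurcation probability per micrometre of grown cable.
#' @param angle_sd standard deviation (degrees) of the per-step direction
#'   perturbation (tortuosity).
#' @param branch_angle total opening angle (degrees) between daughter
#'   branches at a bifurcation.
#' @param step polyline step length (um); one network vertex per step.
#' @param trunk_range range (um) of the initial unbranched trunk (proximal
#'   dendrites carry no bifurcations right at the soma).
#' @return an object of class `dendrite_spec`.
#' @export
dendrite_spec <- function(length_range = c(600, 2400),
                          branch_rate = 0.007,
                          angle_sd = 12,
                          branch_angle = 50,
                          step = 2,
                          trunk_range = c(20, 60)) {
  spec <- list(length_range = as.numeric(length_range),
               branch_rate = as.numeric(branch_rate),
               angle_sd = as.numeric(angle_sd),
               branch_angle = as.numeric(branch_angle),
               step = as.numeric(step),
               trunk_range = as.numeric(trunk_range))
  if (length(spec$length_range) != 2L || any(spec$length_range <= 0) ||
      diff(spec$length_range) < 0) {
    stopf("length_range must be a positive increasing pair")
  }
  if (spec$branch_rate < 0) stopf("branch_rate must be nonnegative")
  if (spec$step <= 0) stopf("step must be positive")
  if (spec$angle_sd < 0 || spec$branch_angle < 0) stopf("angles must be nonnegative")
  structure(spec, class = "dendrite_spec")
}

# random unit vector orthogonal to v
random_perp <- function(v) {
  repeat {
    u <- stats::rnorm(3L)
    u <- u - sum(u * v) * v
    nu <- sqrt(sum(u^2))
    if (nu > 1e-8) return(u / nu)
  }
}

# rotate unit vector v by angle (radians) towards a random orthogonal direction
tilt <- function(v, angle) {
  u <- random_perp(v)
  w <- cos(angle) * v + sin(angle) * u
  w / sqrt(sum(w^2))
}

#' Generate a synthetic dendritic tree
#'
#' Grows a rooted 3D tree by a branching random walk: active tips advance in
#' steps of the tortuosity length with Gaussian angular noise, bifurcate at
#' the stated rate (outside the initial trunk), and growth stops when the
#' drawn target total length is reached. Every polyline step becomes a
#' network vertex, so the result is a valid [build_network()] input and
#' output.
#'
#' @param spec a [dendrite_spec()].
#' @param seed optional integer seed.
#' @return a `linnet3d` rooted at the first vertex.
#' @export
generate_dendrite <- function(spec = dendrite_spec(), seed = NULL) {
  if (!inherits(spec, "dendrite_spec")) stopf("spec must be a dendrite_spec")
  with_seed(seed, {
    target <- stats::runif(1L, spec$length_range[1L], spec$length_range[2L])
    trunk <- stats::runif(1L, spec$trunk_range[1L], spec$trunk_range[2L])
    if (target < spec$step) stopf("target length smaller than one step; tree would be empty")
    step <- spec$step
    p_branch <- min(1, spec$branch_rate * step)
    nmax <- ceiling(target / step) + 16L
    verts <- matrix(NA_real_, nmax, 3L)
    edges <- matrix(NA_integer_, nmax, 2L)
    verts[1L, ] <- 0
    nv <- 1L
    ne <- 0L
    d0 <- stats::rnorm(3L)
    tips <- list(list(at = 1L, dir = d0 / sqrt(sum(d0^2)), from_root = 0))
    grown <- 0
    while (grown < target && length(tips) > 0L) {
      k <- sample.int(length(tips), 1L)
      tip <- tips[[k]]
      dir <- tilt(tip$dir, abs(stats::rnorm(1L, 0, spec$angle_sd * pi / 180)))
      nv <- nv + 1L
      ne <- ne + 1L
      if (nv > nrow(verts)) {
        verts <- rbind(verts, matrix(NA_real_, nmax, 3L))
        edges <- rbind(edges, matrix(NA_integer_, nmax, 2L))
      }
      verts[nv, ] <- verts[tip$at, ] + step * dir
      edges[ne, ] <- c(tip$at, nv)
      grown <- grown + step
      newtip <- list(at = nv, dir = dir, from_root = tip$from_root + step)
      if (newtip$from_root > trunk && stats::runif(1L) < p_branch) {
        half <- spec$branch_angle / 2 * pi / 180
        tips[[k]] <- list(at = nv, dir = tilt(dir, half), from_root = newtip$from_root)
        tips[[length(tips) + 1L]] <-
          list(at = nv, dir = tilt(dir, half), from_root = newtip$from_root)
      } else {
        tips[[k]] <- newtip
      }
    }
    build_network(verts[seq_len(nv), , drop = FALSE],
                  edges[seq_len(ne), , drop = FALSE], root = 1L)
  })
}

#' Generate replicated grouped patterns
#'
#' Builds the fixture for the replicated-pattern permutation test: `g` groups
#' of independent synthetic dendrites, each carrying a pattern simulated from
#' that group's intensity model.
#'
#' @param sizes integer vector of group sizes \eqn{m_1, \dots, m_g}.
#' @param models list of [log_quadratic()] models, one per group.
#' @param spec a [dendrite_spec()] shared by all trees.
#' @param seed optional integer seed (the whole collection is reproducible).
#' @return class `grouped_patterns`: list with `groups`, a list of `g` lists
#'   of `netppp` objects.
#' @export
generate_replicated_groups <- function(sizes, models, spec = dendrite_spec(),
                                       seed = NULL) {
  g <- length(sizes)
  if (g < 2L) stopf("need at least two groups")
  if (length(models) != g) stopf("sizes and models must have the same length (%d vs %d)",
                                 g, length(models))
  with_seed(seed, {
    groups <- lapply(seq_len(g), function(i) {
      lapply(seq_len(sizes[i]), function(j) {
        net <- generate_dendrite(spec)
        simulate_inhom(net, models[[i]])
      })
    })
    structure(list(groups = groups), class = "grouped_patterns")
  })
}

#' @export
print.grouped_patterns <- function(x, ...) {
  sizes <- vapply(x$groups, length, integer(1L))
  ns <- lapply(x$groups, function(gr) vapply(gr, function(p) p$n, integer(1L)))
  cat(sprintf("<grouped_patterns: %d groups of sizes %s>\n",
              length(sizes), paste(sizes, collapse = ", ")))
  for (i in seq_along(ns)) {
    cat(sprintf("  group %d event counts: %s\n", i, paste(ns[[i]], collapse = ", ")))
  }
  invisible(x)
}
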