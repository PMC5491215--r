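# Monte Carlo global envelope test for a single pattern against a Poisson
# null model (homogeneous or log-quadratic inhomogeneous).

summary_curve <- function(pattern, summary, grid) {
  if (summary == "KL") {
    k_corrected(pattern, grid)$value
  } else {
    fit <- suppressWarnings(fit_log_quadratic(pattern))
    k_inhom(pattern, fit, grid)$value
  }
}

simulate_null <- function(net, null_model) {
  for (try in 1:100) {
    pat <- if (inherits(null_model, "logquad")) {
      simulate_inhom(net, null_model)
    } else {
      simulate_csr(net, lambda = as.numeric(null_model))
    }
    if (pat$n >= 2L) return(pat)
  }
  stopf("null model keeps producing patterns with fewer than 2 events")
}

#' Global envelope test for a network point pattern
#'
#' Simulates `n_sim` patterns from the null model on the observed pattern's
#' network, computes the chosen summary function for each, and builds the
#' global envelope of constant width \eqn{2 w_{max}} around the theoretical
#' Poisson curve \eqn{K(d) = d}, where \eqn{w_{max}} is the largest absolute
#' deviation of any simulated summary from the theoretical curve at any grid
#' distance. The null model is rejected when the empirical summary leaves the
#' band; with the default `n_sim = 19` this is a Monte Carlo test at level
#' \eqn{1/(1+19) = 0.05}.
#'
#' For `summary = "KLI"` the log-quadratic intensity is re-fitted to the
#' observed pattern and to every simulated pattern before computing its
#' summary, so the envelope accounts for intensity estimation.
#'
#' @param pattern a `netppp` with at least two events.
#' @param null_model either a numeric CSR rate (events/um) or a
#'   [log_quadratic()] model.
#' @param summary `"KL"` (corrected K) or `"KLI"` (inhomogeneous corrected K).
#' @param n_sim number of null simulations.
#' @param grid a [distance_grid()] or numeric vector within `[0, R]`; default
#'   512 points up to 0.98 R.
#' @param seed optional integer seed.
#' @return class `envelope_test`: list with `curves` (data frame `d`, `value`,
#'   `theoretical`, `lower`, `upper`), `w_max`, `n_sim`, `alpha`
#'   (= 1/(1+n_sim)), `rejected`, `summary`.
#' @export
global_envelope_test <- function(pattern, null_model,
                                 summary = c("KL", "KLI"),
                                 n_sim = 19L, grid = NULL, seed = NULL) {
  summary <- match.arg(summary)
  if (pattern$n < 2L) stopf("envelope test needs at least two events")
  if (n_sim < 1L) stopf("n_sim must be at least 1")
  g <- as_grid_values(grid, pattern$net)
  with_seed(seed, {
    obs <- summary_curve(pattern, summary, g)
    sims <- vapply(seq_len(n_sim), function(b) {
      summary_curve(simulate_null(pattern$net, null_model), summary, g)
    }, numeric(length(g)))
    w_max <- max(abs(sims - g))
    lower <- g - w_max
    upper <- g + w_max
    rejected <- any(obs < lower | obs > upper)
    structure(list(
      curves = data.frame(d = g, value = obs, theoretical = g,
                          lower = lower, upper = upper),
      w_max = w_max, n_sim = as.integer(n_sim), alpha = 1 / (1 + n_sim),
      rejected = rejected, summary = summary
    ), class = "envelope_test")
  })
}

#' @export
print.envelope_test <- function(x, ...) {
  cat(sprintf("Global envelope test (%s, %d simulations, level %.3f)\n",
              x$summary, x$n_sim, x$alpha))
  cat(sprintf("  w_max = %.4f um; null model %s\n", x$w_max,
              if (x$rejected) "REJECTED (summary leaves the envelope)" else "not rejected"))
  invisible(x)
}

#' @export
plot.envelope_test <- function(x, ..., xlab = "d (um)", ylab = x$summary) {
  cv <- x$curves
  graphics::plot(cv$d, cv$upper, type = "n", xlab = xlab, ylab = ylab,
                 ylim = range(cv$lower, cv$upper, cv$value), ...)
  graphics::polygon(c(cv$d, rev(cv$d)), c(cv$lower, rev(cv$upper)),
                    col = "grey85", border = NA)
  graphics::lines(cv$d, cv$theoretical, lty = 2, col = "red")
  graphics::lines(cv$d, cv$value)
  invisible(x)
}
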