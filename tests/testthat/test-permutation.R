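# H statistic and the studentized permutation test.

# build a netsumfun-like curve on a grid for h_statistic input
curve_on <- function(grid, values) {
  out <- data.frame(d = grid, value = values, theoretical = grid)
  class(out) <- c("netsumfun", "data.frame")
  out
}

test_that("H is zero for groups with identical means and symmetric in labels", {
  grid <- seq(0, 10, length.out = 21)
  a <- curve_on(grid, grid * 1.1)
  b <- curve_on(grid, grid * 0.9)
  # the two groups hold permutations of the same pair of curves
  expect_equal(h_statistic(list(list(a, b), list(b, a)), 0, 10), 0)
  g1 <- list(curve_on(grid, grid), curve_on(grid, grid^1.1))
  g2 <- list(curve_on(grid, sqrt(grid) * 2), curve_on(grid, grid * 0.5))
  h12 <- h_statistic(list(g1, g2), 1, 9)
  expect_equal(h_statistic(list(g2, g1), 1, 9), h12)
  expect_equal(h_statistic(list(rev(g1), g2), 1, 9), h12)
})

test_that("H matches a symbolic evaluation on a tiny hand-built design", {
  # 2 groups x 2 patterns x 2 grid points
  grid <- c(0, 1)
  g1 <- list(curve_on(grid, c(1, 3)), curve_on(grid, c(3, 5)))
  g2 <- list(curve_on(grid, c(0, 1)), curve_on(grid, c(2, 1)))
  # group means: (2,4) and (1,1); difference (1,3); integral of (T1-T2)^2 by
  # trapezoid on [0,1]: (1 + 9)/2 = 5.
  # within-group squared deviations: group1 curves are mean +/- (1,1) so
  # var(d) = 2*(1)^2/(2-1)... per definition (1/(m-1)) sum = 2 at both d,
  # time-average 2; group2: deviations (+/-1, 0), sum/(m-1) = 2 at d=0, 0 at
  # d=1, time-average (2+0)/2 = 1.
  # denominator: 2/2 + 1/2 = 1.5; H = 5 / 1.5
  expect_equal(h_statistic(list(g1, g2), 0, 1), 5 / 1.5)
})

test_that("constant-in-d summaries reduce H to a scaled two-sample t statistic", {
  set.seed(90)
  grid <- seq(2, 8, length.out = 33)
  x <- rnorm(5, 10, 2)
  y <- rnorm(4, 8, 2)
  gx <- lapply(x, function(v) curve_on(grid, rep(v, length(grid))))
  gy <- lapply(y, function(v) curve_on(grid, rep(v, length(grid))))
  H <- h_statistic(list(gx, gy), 2, 8)
  tstat2 <- (mean(x) - mean(y))^2 / (var(x) / 5 + var(y) / 4)
  expect_equal(H, (8 - 2) * tstat2, tolerance = 1e-10)
})

test_that("degenerate variance conventions: 0/0 pairs drop, x/0 is infinite", {
  grid <- seq(0, 1, length.out = 5)
  same <- list(curve_on(grid, grid), curve_on(grid, grid))
  expect_equal(h_statistic(list(same, same), 0, 1), 0)
  other <- list(curve_on(grid, grid + 1), curve_on(grid, grid + 1))
  expect_identical(h_statistic(list(same, other), 0, 1), Inf)
  expect_error(h_statistic(list(same, list(curve_on(grid, grid))), 0, 1),
               "single pattern")
  expect_error(h_statistic(list(same, same), 0, 2), "does not cover")
})

test_that("identical patterns give p = 1 and p is seed-stable", {
  set.seed(91)
  net <- generate_dendrite(small_spec())
  pat <- simulate_csr(net, fixed_n = 25)
  groups <- list(list(pat, pat), list(pat, pat))
  res <- suppressWarnings(
    studentized_permutation_test(groups, n_perm = 49, seed = 92))
  expect_equal(res$p_value, 1)
  res2 <- suppressWarnings(
    studentized_permutation_test(groups, n_perm = 49, seed = 92))
  expect_identical(res$h_permuted, res2$h_permuted)
  expect_gt(res$p_value, 0) # the +1 convention forbids p = 0
})

test_that("default d1 follows the 2%-below-minimum-circumradius rule", {
  set.seed(93)
  gp <- generate_replicated_groups(c(3, 3), list(log_quadratic(log(0.4)),
                                                 log_quadratic(log(0.4))),
                                   small_spec(), seed = 94)
  pats <- unlist(gp$groups, recursive = FALSE)
  Rmin <- min(vapply(pats, function(p) circumradius(p$net), numeric(1)))
  res <- studentized_permutation_test(gp, n_perm = 19, seed = 95)
  expect_equal(res$interval[["d1"]], 0.98 * Rmin)
  expect_error(
    studentized_permutation_test(gp, d1 = Rmin * 1.2, n_perm = 19),
    "exceeds the circumradius")
  expect_warning(
    studentized_permutation_test(list(gp$groups[[1]][1:2], gp$groups[[2]][1:2]),
                                 n_perm = 9, seed = 96),
    "fewer than three")
})

test_that("the test separates clearly different spine distributions", {
  set.seed(97)
  spec <- small_spec()
  flat <- log_quadratic(log(0.5))
  gp <- generate_replicated_groups(c(4, 4), list(flat, flat), spec, seed = 98)
  # replace group 2's patterns by strongly clustered ones on their networks
  gp$groups[[2]] <- lapply(gp$groups[[2]], function(p) {
    net <- p$net
    seg <- which.max(net$lengths)
    suppressWarnings(net_pattern(net, netloc(rep(seg, max(10, p$n)),
                                             runif(max(10, p$n), 0, min(2, net$lengths[seg])))))
  })
  res <- studentized_permutation_test(gp, n_perm = 199, seed = 99)
  expect_lt(res$p_value, 0.05)
})

test_that("permutation p-values are sub-uniform under exchangeability", {
  set.seed(100)
  spec <- small_spec()
  flat <- list(log_quadratic(log(0.35)), log_quadratic(log(0.35)))
  pv <- replicate(30, {
    gp <- generate_replicated_groups(c(3, 3), flat, spec)
    studentized_permutation_test(gp, n_perm = 39, grid_size = 64)$p_value
  })
  n_perm <- 39
  expect_lte(mean(pv <= 0.1), 0.1 + 1 / (n_perm + 1) + 3 * sqrt(0.1 * 0.9 / 30))
})
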