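# Network geometry: construction, shortest-path distances, m(u,t),
# circumradius, snapping.

test_that("build_network computes segment lengths and |L| from coordinates", {
  net <- seg_net(3)
  expect_equal(net$total_length, 3)
  y <- y_net()
  expect_equal(y$total_length, 10)
  expect_equal(sort(y$lengths), c(3, 3, 4))
  # |L| equals an independent re-summation over polyline edges
  set.seed(11)
  t1 <- generate_dendrite(small_spec())
  relen <- sum(sqrt(rowSums((t1$vertices[t1$edges[, 1], ] - t1$vertices[t1$edges[, 2], ])^2)))
  expect_equal(t1$total_length, relen)
})

test_that("build_network rejects degenerate graphs", {
  v4 <- matrix(runif(12), 4, 3)
  expect_error(build_network(v4, rbind(c(1, 2), c(3, 4))), "disconnected")
  expect_error(build_network(v4, rbind(c(1, 2), c(2, 3), c(3, 1), c(3, 4))), "cycle")
  vdup <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))
  expect_error(build_network(vdup, rbind(c(1, 2), c(2, 3))), "zero-length")
  expect_error(build_network(v4, rbind(c(1, 1), c(2, 3), c(3, 4))), "distinct")
  expect_error(build_network(v4, rbind(c(1, 2), c(2, 3), c(3, 5))), "out of range")
})

test_that("shortest-path distance: identity, same-segment, symmetry", {
  net <- seg_net(10)
  u <- netloc(1, 2); v <- netloc(1, 6)
  expect_equal(shortest_path_distance(net, u, u), 0)
  expect_equal(shortest_path_distance(net, u, v), 4)
  expect_equal(shortest_path_distance(net, v, u), 4)
  y <- y_net()
  expect_equal(distance_to_root(y, netloc(1, 0)), 0)
  expect_equal(distance_to_root(y, netloc(2, 3)), 7) # tip via the trunk
})

test_that("locations at a shared vertex compare equal across incident segments", {
  y <- y_net() # segment 1 ends and segments 2,3 start at vertex 2
  reps <- list(netloc(1, 4), netloc(2, 0), netloc(3, 0))
  for (a in reps) for (b in reps) {
    expect_equal(shortest_path_distance(y, a, b), 0)
  }
  expect_equal(count_at_distance(y, netloc(1, 4), 2),
               count_at_distance(y, netloc(2, 0), 2))
})

test_that("shortest-path distances match a brute-force Dijkstra oracle", {
  set.seed(42)
  for (rep in 1:10) {
    net <- rtree_net(nv = sample(5:15, 1))
    loc <- runif_locs(net, 8)
    D <- pair_distances(net, loc)
    for (i in 1:7) {
      d_oracle <- oracle_loc_dist(net, loc[i], loc[i + 1])
      expect_equal(shortest_path_distance(net, loc[i], loc[i + 1]), d_oracle,
                   tolerance = 1e-6)
      expect_equal(D[i, i + 1], d_oracle, tolerance = 1e-6)
    }
    # triangle inequality on the pair matrix
    for (k in 1:3) {
      ijk <- sample(nrow(D), 3)
      expect_lte(D[ijk[1], ijk[2]],
                 D[ijk[1], ijk[3]] + D[ijk[3], ijk[2]] + 1e-9)
    }
    # distance to root agrees with the oracle
    dr <- distance_to_root(net, loc)
    g0 <- netloc(net$first_seg[net$root],
                 if (net$vertex_at_start[net$root]) 0 else net$lengths[net$first_seg[net$root]])
    for (i in seq_along(dr)) {
      expect_equal(dr[i], oracle_loc_dist(net, loc[i], g0), tolerance = 1e-6)
    }
  }
})

test_that("count_at_distance follows the exact two-front rule on a segment", {
  net <- seg_net(10)
  u <- netloc(1, 3)
  expect_identical(count_at_distance(net, u, 2), 2L)
  expect_identical(count_at_distance(net, u, 7), 1L) # far endpoint vertex
  expect_identical(count_at_distance(net, u, 8), 0L)
  expect_identical(count_at_distance(net, u, 0), 1L)
  expect_identical(count_at_distance(net, u, 3), 2L) # near endpoint vertex + one front
  expect_error(count_at_distance(net, u, -1), "nonnegative")
  # hub of a 3-arm star sees three fronts
  expect_identical(count_at_distance(star_net(), netloc(1, 0), 1.5), 3L)
})

test_that("count_at_distance agrees with the discretization oracle", {
  set.seed(7)
  for (rep in 1:8) {
    net <- rtree_net(nv = sample(5:10, 1), scale = 8)
    u <- runif_locs(net, 1)
    ecc <- max(oracle_vertex_dists(net, u)) # farthest point of a tree is a vertex
    for (t in runif(4, 0.05, ecc * 0.95)) {
      expect_identical(count_at_distance(net, u, t), as.integer(oracle_m(net, u, t)),
                       label = sprintf("m(u, %.4f), rep %d", t, rep))
    }
    # positive inside the eccentricity, zero beyond it
    expect_gt(count_at_distance(net, u, ecc * 0.5), 0)
    expect_identical(count_at_distance(net, u, ecc * 1.01), 0L)
  }
})

test_that("circumradius equals half the continuum diameter", {
  expect_equal(circumradius(seg_net(10)), 5)
  expect_equal(circumradius(star_net(c(3, 4, 5))), 4.5)
  set.seed(99)
  for (rep in 1:5) {
    net <- rtree_net(nv = 8, scale = 6)
    # sampling every 1e-3 um bounds the oracle's error by 5e-4 (unit slope)
    expect_equal(circumradius(net), oracle_circumradius(net, spacing = 1e-3),
                 tolerance = 1e-3)
  }
})

test_that("circumradius is consistent with the sup definition of m", {
  set.seed(5)
  net <- rtree_net(nv = 10)
  R <- circumradius(net)
  for (u in list(runif_locs(net, 1), runif_locs(net, 1), netloc(1, 0))) {
    for (t in runif(3, 0, R * 0.999)) {
      expect_gt(count_at_distance(net, u, t), 0)
    }
  }
})

test_that("rigid motion leaves lengths, distances, m and R unchanged", {
  set.seed(21)
  net <- rtree_net(nv = 10)
  net2 <- build_network(rigid_motion(net$vertices), net$edges, root = net$root)
  expect_equal(net2$total_length, net$total_length)
  expect_equal(circumradius(net2), circumradius(net))
  loc <- runif_locs(net, 6)
  expect_equal(pair_distances(net2, loc), pair_distances(net, loc))
  u <- loc[1]
  ts <- runif(5, 0, circumradius(net))
  expect_identical(count_at_distance(net2, u, ts), count_at_distance(net, u, ts))
})

test_that("a z-constant network behaves exactly like its 2D projection", {
  set.seed(31)
  v <- matrix(runif(30, 0, 20), 10, 3)
  v[, 3] <- 7.5
  parent <- vapply(2:10, function(i) sample.int(i - 1L, 1L), integer(1))
  e <- cbind(parent, 2:10)
  net3 <- build_network(v, e)
  v2 <- v; v2[, 3] <- 0
  net2 <- build_network(v2, e)
  expect_identical(net3$lengths, net2$lengths)
  loc <- runif_locs(net3, 8)
  expect_identical(pair_distances(net3, loc), pair_distances(net2, loc))
  expect_identical(circumradius(net3), circumradius(net2))
})

test_that("snapping projects points orthogonally and reports failures", {
  net <- seg_net(10)
  s <- snap_to_network(net, c(4, 1, 0), max_dist = 2)
  expect_equal(s$seg, 1L)
  expect_equal(s$offset, 4)
  expect_equal(attr(s, "residual"), 1)
  on <- snap_to_network(net, c(7, 0, 0), max_dist = 1)
  expect_equal(on$offset, 7)
  expect_equal(attr(on, "residual"), 0)
  expect_error(snap_to_network(net, c(5, 10, 0), max_dist = 2), "10.000")
  expect_error(snap_to_network(net, c(5, 1, 0), max_dist = 0), "positive")
})

test_that("snapping recovers perturbed on-network locations", {
  set.seed(77)
  net <- generate_dendrite(small_spec())
  loc <- runif_locs(net, 60)
  a <- net$edges[loc$seg, 1]; b <- net$edges[loc$seg, 2]
  frac <- loc$offset / net$lengths[loc$seg]
  xyz <- net$vertices[a, ] * (1 - frac) + net$vertices[b, ] * frac
  sigma <- 0.2
  noisy <- xyz + matrix(rnorm(length(xyz), 0, sigma), ncol = 3)
  snapped <- snap_to_network(net, noisy, max_dist = 5)
  err <- shortest_path_distance(net, loc, snapped)
  expect_lte(unname(quantile(err, 0.95)), 3 * sigma)
})
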