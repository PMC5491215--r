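# Small fixtures built in code.

# single straight segment of given length along x
seg_net <- function(len = 10) {
  build_network(rbind(c(0, 0, 0), c(len, 0, 0)), cbind(1, 2))
}

# Y-shaped tree: trunk of length 4 up z, two branches of length 3
y_net <- function() {
  v <- rbind(c(0, 0, 0), c(0, 0, 4), c(3, 0, 4), c(0, 3, 4))
  build_network(v, rbind(c(1, 2), c(2, 3), c(2, 4)))
}

# star with three straight arms of given lengths from a hub at the origin
star_net <- function(arms = c(3, 4, 5)) {
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(-1, 0, 0), c(0, -1, 0))
  v <- rbind(c(0, 0, 0), dirs[seq_along(arms), , drop = FALSE] * arms)
  build_network(v, cbind(1L, 1L + seq_along(arms)))
}

# random tree: vertex i >= 2 attaches to a uniformly chosen earlier vertex;
# coordinates are uniform in a box (distinct with probability 1)
rtree_net <- function(nv = 12, scale = 20) {
  v <- matrix(stats::runif(nv * 3, 0, scale), nv, 3)
  parent <- vapply(2:nv, function(i) sample.int(i - 1L, 1L), integer(1))
  build_network(v, cbind(parent, 2:nv), root = 1L)
}

# uniform random locations on a network (by arc length), without using the
# package's simulators
runif_locs <- function(net, n) {
  seg <- sample.int(nrow(net$edges), n, replace = TRUE, prob = net$lengths)
  netloc(seg, stats::runif(n) * net$lengths[seg])
}

# small synthetic dendrite spec used to keep simulation-heavy tests fast;
# problem sizes are documented in the methods vignette
small_spec <- function() {
  dendrite_spec(length_range = c(250, 400), branch_rate = 0.015,
                step = 4, trunk_range = c(10, 30))
}
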