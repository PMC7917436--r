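# Independent numerical oracles used across the suite.

# Brute-force 3-D grid quadrature of the pseudo-density overlap integral,
# independent of the closed-form path in the package.
grid_overlap_oracle <- function(a, b, spacing = 0.05, padding = 12) {
  all_c <- rbind(a$centers, b$centers)
  lo <- apply(all_c, 2, min) - padding
  hi <- apply(all_c, 2, max) + padding
  xs <- seq(lo[1], hi[1], by = spacing)
  ys <- seq(lo[2], hi[2], by = spacing)
  zs <- seq(lo[3], hi[3], by = spacing)
  xy <- expand.grid(x = xs, y = ys)
  dens_slice <- function(d, z) {
    v <- numeric(nrow(xy))
    for (i in seq_len(nrow(d$centers))) {
      s2 <- d$sigma[i]^2
      r2 <- (xy$x - d$centers[i, 1])^2 + (xy$y - d$centers[i, 2])^2 +
            (z - d$centers[i, 3])^2
      v <- v + (2 * pi * s2)^(-1.5) * exp(-r2 / (2 * s2))
    }
    v
  }
  tot <- 0
  for (z in zs) tot <- tot + sum(dens_slice(a, z) * dens_slice(b, z))
  tot * spacing^3
}

# Random rigid motion (proper rotation + translation) applied to a frameset.
apply_rigid_motion <- function(frames, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- rnorm(3, 0, 20)
  xyz <- frames$xyz
  for (f in seq_len(nrow(xyz))) {
    co <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    xyz[f, ] <- as.vector(t(co %*% t(q) + matrix(shift, nrow(co), 3, byrow = TRUE)))
  }
  frameset(frames$atoms, xyz)
}

# Area of a lineshape inside a window centered on each vibronic peak.
peak_areas <- function(ls, spacing, n_max, half_width = spacing / 2) {
  sapply(0:n_max, function(n) {
    w <- ls$grid >= n * spacing - half_width & ls$grid < n * spacing + half_width
    pracma::trapz(ls$grid[w], ls$intensity[w])
  })
}

# Mean length of completed same-state runs in a label sequence.
mean_dwell_frames <- function(s) {
  r <- rle(s)
  len <- r$lengths
  if (length(len) > 2) len <- len[2:(length(len) - 1)]  # drop censored ends
  mean(len)
}

# Three planted pocket conformations (fractions of in/in, out/in, out/out)
# under fast-mixing dynamics suitable for population estimation at a few
# thousand frames.
planted_three_class_config <- function(n_frames, pops = c(0.78, 0.17, 0.05),
                                       seed = 1, class_dwell = 4) {
  synthetic_config(
    n_frames = n_frames,
    classes = list(
      list(name = "IN",    population = pops[1],
           states = c(Q489 = "in",  N468 = "in")),
      list(name = "OUT_A", population = pops[2],
           states = c(Q489 = "out", N468 = "in")),
      list(name = "OUT_B", population = pops[3],
           states = c(Q489 = "out", N468 = "out"))),
    class_dwell = class_dwell,
    seed = seed)
}
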