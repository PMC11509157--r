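# shared fixtures: small scenarios and brute-force oracles

small_scenario <- function(n_points = 60, ...) {
  orchard_scenario(border_length = 400, n_points = n_points, seed = 1, ...)
}

# per-fruit expansion oracle for severity: replicate each injured class's
# V by its count and average
brute_severity <- function(class_counts, scheme = damage_class_scheme()) {
  v <- rep(scheme$V[-1L], class_counts[-1L])
  if (length(v) == 0L) return(NA_real_)
  mean(v)
}

# dense-sampling oracle for point-to-polyline distance
brute_min_distance <- function(points, vertices, samples_per_segment = 1e4) {
  seg_a <- vertices[-nrow(vertices), , drop = FALSE]
  seg_b <- vertices[-1L, , drop = FALSE]
  t <- seq(0, 1, length.out = samples_per_segment)
  sx <- c(t(outer(seg_a[, 1L], t, function(a, t) a) +
             outer(seg_b[, 1L] - seg_a[, 1L], t)))
  sy <- c(t(outer(seg_a[, 2L], t, function(a, t) a) +
             outer(seg_b[, 2L] - seg_a[, 2L], t)))
  apply(points, 1L, function(p) sqrt(min((p[1L] - sx)^2 + (p[2L] - sy)^2)))
}

random_class_counts <- function(n, scheme = damage_class_scheme()) {
  k <- nrow(scheme)
  m <- matrix(rpois(n * k, lambda = c(60, rep(3, k - 1L))), n, k, byrow = TRUE)
  m
}
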