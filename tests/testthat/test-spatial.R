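test_that("point-to-segment distance handles foot-inside and nearest-vertex cases", {
  b <- border_polyline(rbind(c(0, 0), c(10, 0)))
  expect_equal(min_distance_to_border(c(5, 7), b), 7)
  expect_equal(min_distance_to_border(c(-3, 4), b), 5)  # 3-4-5 triangle
  expect_equal(min_distance_to_border(c(4, 0), b), 0)
  expect_error(border_polyline(rbind(c(0, 0))), "n >= 2")
  expect_error(border_polyline(rbind(c(0, 0), c(0, 0))), "distinct")
})

test_that("polyline distance matches the dense-sampling oracle", {
  set.seed(11)
  v <- cbind(sort(runif(28, 0, 100)), runif(28, 0, 100))
  pts <- cbind(runif(20, 0, 100), runif(20, 0, 100))
  d <- min_distance_to_border(pts, border_polyline(v))
  d_brute <- brute_min_distance(pts, v, samples_per_segment = 1e4)
  expect_true(all(d <= d_brute + 1e-12))  # exact min is a lower bound
  expect_true(all(abs(d - d_brute) < 1e-3))
})

test_that("border distance is invariant under rigid rotation and translation", {
  set.seed(12)
  v <- cbind(runif(10, 0, 50), runif(10, 0, 50))
  pts <- cbind(runif(15, 0, 50), runif(15, 0, 50))
  d0 <- min_distance_to_border(pts, border_polyline(v))
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  shift <- c(123.4, -56.7)
  d1 <- min_distance_to_border(sweep(pts %*% R, 2L, shift, "+"),
                               border_polyline(sweep(v %*% R, 2L, shift, "+")))
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("the distance matrix is Euclidean and consistent with nearest-trap distances", {
  dm <- distance_matrix(c(0, 0), rbind(c(0, 0), c(3, 4)))
  expect_equal(as.vector(dm), c(0, 5))
  set.seed(13)
  pts <- cbind(runif(30, 0, 100), runif(30, 0, 100))
  traps <- cbind(runif(6, 0, 100), runif(6, 0, 100))
  dm2 <- distance_matrix(pts, traps)
  byhand <- vapply(seq_len(30), function(i)
    min(sqrt(colSums((t(traps) - pts[i, ])^2))), numeric(1L))
  expect_equal(nearest_trap_distance(dm2), byhand)
})

test_that("both catch index variants reproduce hand arithmetic", {
  expect_equal(catch_index(100, 10), 1)
  expect_equal(catch_index(100, 10, variant = "text"), 10)
  expect_equal(catch_index(c(50, 50), c(10, 20)), 0.625)
  expect_equal(catch_index(c(50, 50), c(10, 20), variant = "text"),
               sqrt(25 + 6.25))
  expect_equal(catch_index(c(0, 0), c(10, 20)), 0)
  expect_equal(catch_index(c(0, 0), c(10, 20), variant = "text"), 0)
  expect_error(catch_index(5, 0), "zero distance")
})

test_that("catch index is 1-homogeneous in catches and decreases with distance", {
  set.seed(14)
  H <- rpois(5, 200)
  d <- runif(5, 5, 80)
  for (v in c("displayed", "text")) {
    expect_equal(catch_index(2 * H, d, variant = v),
                 2 * catch_index(H, d, variant = v))
    expect_lt(catch_index(H, d * 1.5, variant = v),
              catch_index(H, d, variant = v))
  }
})

test_that("lon/lat projection gives metric distances on small extents", {
  # one degree of latitude is ~111.2 km; longitude shrinks by cos(lat)
  ll <- rbind(c(11.18, 46.61), c(11.18, 46.62), c(11.19, 46.61))
  xy <- lonlat_to_local(ll, center = c(11.18, 46.61))
  expect_equal(xy[1L, ], c(x = 0, y = 0))
  expect_equal(unname(xy[2L, 2L]), 1111.949, tolerance = 1e-3)
  expect_equal(unname(xy[3L, 1L]), 1111.949 * cos(46.61 * pi / 180),
               tolerance = 1e-3)
})
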