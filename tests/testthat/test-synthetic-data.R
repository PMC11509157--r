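test_that("invalid scenarios are rejected", {
  expect_error(orchard_scenario(depth = 0), "depth")
  expect_error(orchard_scenario(n_points = 0), "n_points")
  expect_error(orchard_scenario(male_sail_fraction = 1.2), "\\[0, 1\\]")
  expect_error(orchard_scenario(catch_dispersion = -1), "catch_dispersion")
  expect_error(generate_trap_catches(small_scenario(), dates = c("a", "b")),
               "lengths differ")
})

test_that("one seed yields a bit-identical trial", {
  sc <- small_scenario()
  expect_identical(generate_assessment_points(sc),
                   generate_assessment_points(sc))
  expect_identical(generate_trap_catches(sc), generate_trap_catches(sc))
  expect_identical(generate_trial(sc), generate_trial(sc))
})

test_that("class counts are consistent and fruit totals sit near the scenario mean", {
  sc <- small_scenario(n_points = 150)
  pts <- generate_assessment_points(sc)
  counts <- as.matrix(pts[, paste0("n_class", 1:6)])
  expect_true(all(counts >= 0))
  expect_equal(mean(rowSums(counts)), 92, tolerance = 0.01)
  expect_true(all(pts$x >= 0 & pts$x <= sc$border_length))
  expect_true(all(pts$y >= 0 & pts$y <= sc$depth))
})

test_that("flat decay with no heterogeneity gives the stated incidence level", {
  sc <- orchard_scenario(n_points = 400, seed = 3,
                         incidence_intercept_control = log(0.1),
                         incidence_slope_control = 0,
                         incidence_intercept_trap = log(0.1),
                         incidence_slope_trap = 0,
                         incidence_sd_log = 0)
  pts <- generate_assessment_points(sc)
  inc <- damage_incidence(as.matrix(pts[, paste0("n_class", 1:6)]))
  expect_equal(mean(inc), 10, tolerance = 0.5)
})

test_that("a trap-side decay concentrates damage near the border", {
  near <- numeric(50)
  far <- numeric(50)
  for (r in 1:50) {
    sc <- orchard_scenario(n_points = 200, seed = 100 + r,
                           incidence_slope_trap = -0.05,
                           incidence_slope_control = 0)
    pts <- generate_assessment_points(sc)
    d <- min_distance_to_border(as.matrix(pts[, c("x", "y")]),
                                scenario_border(sc))
    inc <- damage_incidence(as.matrix(pts[, paste0("n_class", 1:6)]))
    tr <- pts$has_traps
    near[r] <- mean(inc[tr & d < 20])
    far[r] <- mean(inc[tr & d > 60])
  }
  expect_lt(t.test(near, far, alternative = "greater",
                   paired = TRUE)$p.value, 0.01)
})

test_that("per-trap totals obey the law of large numbers at high dispersion", {
  totals <- numeric(60)
  for (r in 1:60) {
    sc <- orchard_scenario(border_length = 1600, seed = 200 + r,
                           catch_mean_by_date = setNames(rep(100, 6),
                                                         paste0("d", 1:6)),
                           catch_dispersion = 1e6)
    cc <- generate_trap_catches(sc)
    totals[r] <- mean(tapply(cc$count, cc$trap_id, sum))
  }
  expect_equal(mean(totals), 600, tolerance = 0.05 * 600)
})

test_that("the sex split honours the scenario ratio and its boundaries", {
  sc <- small_scenario(sex_ratio_mf = 1)
  cc <- generate_trap_catches(sc)
  tot <- tapply(cc$count, cc$sex, sum)
  expect_equal(unname(tot["male"] / tot["female"]), 1, tolerance = 0.15)

  sc2 <- small_scenario(male_sail_fraction = 1)
  cc2 <- generate_trap_catches(sc2)
  expect_equal(sum(cc2$count[cc2$sex == "male" & cc2$part == "bin"]), 0)

  # convergence of the pooled per-trap ratio at high catch means
  sc3 <- orchard_scenario(seed = 5, catch_mean_by_date = setNames(
    rep(500, 6), paste0("d", 1:6)))
  cc3 <- generate_trap_catches(sc3)
  tot3 <- tapply(cc3$count, cc3$sex, sum)
  expect_equal(unname(tot3["male"] / tot3["female"]), 0.85,
               tolerance = 0.03 * 0.85)
})

test_that("trap positions sit outside the border at the configured standoff", {
  sc <- orchard_scenario()
  expect_true(all(sc$trap_positions[, 2L] == -7))
  expect_equal(nrow(sc$trap_positions), 8L)  # two trap plots, four traps each
  gaps <- diff(sort(sc$trap_positions[1:4, 1L]))
  expect_true(all(gaps >= 40 & gaps <= 50))
})
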