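test_that("curve prediction follows the log-link algebra", {
  set.seed(41)
  d <- data.frame(distance_to_border = runif(150, 0, 100))
  d$y <- rpois(150, exp(3 - 0.04 * d$distance_to_border))
  f <- fit_count_model(y ~ distance_to_border, d)
  grid <- seq(2, 90, by = 0.5)
  cv <- predict_curve(f, grid)
  k <- -coef(f)[["distance_to_border"]]
  n <- length(grid) - 20L
  expect_equal(cv$fit[seq_len(n) + 20L] / cv$fit[seq_len(n)],
               rep(exp(-10 * k), n), tolerance = 1e-10)

  expect_warning(predict_curve(f, seq(0, 150, 10)), "extrapolates")
  expect_error(predict_curve(fit_count_model(y ~ 1, d), grid),
               "distance term")
})

test_that("delta-method standard errors match a parametric bootstrap", {
  set.seed(42)
  d <- data.frame(distance_to_border = runif(200, 0, 100))
  d$y <- rpois(200, exp(3 - 0.03 * d$distance_to_border))
  f <- fit_count_model(y ~ distance_to_border, d)
  grid <- c(5, 25, 50, 75)
  cv <- predict_curve(f, grid)
  draws <- MASS::mvrnorm(2000, coef(f), vcov(f))
  X <- cbind(1, grid)
  boot_sd <- apply(exp(X %*% t(draws)), 1L, sd)
  expect_equal(cv$se, boot_sd, tolerance = 0.1)
})

test_that("d50 is exact for flat curves and matches the truncated-exponential median", {
  grid <- seq(0, 100, by = 0.5)
  expect_equal(cumulated_d50(grid, rep(4, length(grid))), 50)

  k <- 0.05; L <- 100
  closed <- -log(1 - 0.5 * (1 - exp(-k * L))) / k
  expect_equal(cumulated_d50(grid, exp(-k * grid)), closed, tolerance = 0.1)
  # halving the step moves d50 by well under 0.1 m on smooth curves
  fine <- seq(0, 100, by = 0.25)
  expect_lt(abs(cumulated_d50(fine, exp(-k * fine)) -
                  cumulated_d50(grid, exp(-k * grid))), 0.1)

  expect_error(cumulated_d50(grid, rep(0, length(grid))), "zero total area")
  expect_error(cumulated_d50(grid, rep(-1, length(grid))), "nonnegative")
})

test_that("mass concentrated at the border yields a smaller d50 than a flat curve", {
  grid <- seq(0, 100, by = 0.5)
  expect_lt(cumulated_d50(grid, exp(-0.05 * grid)),
            cumulated_d50(grid, rep(1, length(grid))))
})

test_that("the differential effect recovers the analytic crossover", {
  grid <- seq(0, 100, by = 0.5)
  control <- data.frame(distance = grid, fit = rep(10, length(grid)), se = 0.5)
  trap <- data.frame(distance = grid, fit = 20 * exp(-grid / 20), se = 0.5)
  de <- differential_effect(control, trap)
  expect_equal(de$crossover, 20 * log(2), tolerance = 0.01)
  expect_equal(de$curve$se, rep(sqrt(0.5), length(grid)))
  # control - trap is negative before the crossover (trap damage higher)
  expect_true(all(de$curve$difference[grid < 13] < 0))
})

test_that("the differential effect is antisymmetric and honest about no crossing", {
  grid <- seq(0, 100, by = 0.5)
  a <- data.frame(distance = grid, fit = 10 + 0.05 * grid, se = 1)
  b <- data.frame(distance = grid, fit = 20 * exp(-grid / 20), se = 1)
  de <- differential_effect(a, b)
  flipped <- differential_effect(b, a)
  expect_equal(flipped$curve$difference, -de$curve$difference)
  expect_equal(flipped$crossover, de$crossover, tolerance = 1e-9)

  same <- differential_effect(a, a)
  expect_true(all(same$curve$difference == 0))
  expect_true(is.na(same$crossover))

  never <- differential_effect(a, data.frame(distance = grid,
                                             fit = a$fit + 3, se = 1))
  expect_true(is.na(never$crossover))

  short <- data.frame(distance = grid[-1L], fit = b$fit[-1L], se = 1)
  expect_error(differential_effect(a, short), "same distance grid")
})
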