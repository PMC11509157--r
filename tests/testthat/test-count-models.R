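test_that("Poisson MLE reproduces closed forms with and without offsets", {
  d <- data.frame(y = c(2, 4, 6))
  f <- fit_count_model(y ~ 1, d)
  expect_equal(unname(coef(f)), log(4), tolerance = 1e-8)
  expect_equal(unname(fitted(f)), rep(4, 3), tolerance = 1e-8)

  d$e <- c(1, 1, 2)
  f2 <- fit_count_model(y ~ 1 + offset(log(e)), d)
  expect_equal(unname(coef(f2)), log(3), tolerance = 1e-8)
})

test_that("responses must be nonnegative whole counts on a full-rank design", {
  expect_error(fit_count_model(y ~ 1, data.frame(y = c(-1, 2))), "negative")
  expect_error(fit_count_model(y ~ 1, data.frame(y = c(1.5, 2))), "integer")
  d <- data.frame(y = rpois(10, 5), a = 1:10, b = 2 * (1:10))
  expect_error(fit_count_model(y ~ a + b, d), "rank-deficient")
})

test_that("scaling every exposure by k shifts only the intercept by -log k", {
  set.seed(21)
  d <- data.frame(x = rnorm(80), e = runif(80, 0.5, 2))
  d$y <- rpois(80, 3 * d$e * exp(0.4 * d$x))
  f1 <- fit_count_model(y ~ x + offset(log(e)), d)
  d2 <- transform(d, e = 5 * e)
  f2 <- fit_count_model(y ~ x + offset(log(e)), d2)
  expect_equal(coef(f2)[["(Intercept)"]], coef(f1)[["(Intercept)"]] - log(5),
               tolerance = 1e-7)
  expect_equal(coef(f2)[["x"]], coef(f1)[["x"]], tolerance = 1e-7)
})

test_that("negative binomial at huge fixed theta reproduces the Poisson fit", {
  set.seed(22)
  d <- data.frame(x = rnorm(120))
  d$y <- rpois(120, exp(1 + 0.5 * d$x))
  fp <- fit_count_model(y ~ x, d)
  fnb <- glm(y ~ x, data = d, family = MASS::negative.binomial(theta = 1e7))
  expect_equal(unname(coef(fnb)), unname(coef(fp)), tolerance = 1e-4)
})

test_that("negative binomial fits recover the generating coefficients", {
  set.seed(23)
  bias <- replicate(40, {
    x <- rnorm(500)
    y <- rnbinom(500, mu = exp(log(5) + 0.5 * x), size = 2)
    f <- suppressWarnings(
      fit_count_model(y ~ x, data.frame(x = x, y = y), "negative_binomial"))
    abs(coef(f) - c(log(5), 0.5))
  })
  expect_lt(median(bias[1L, ]), 0.05)
  expect_lt(median(bias[2L, ]), 0.05)
})

test_that("the likelihood-ratio deviance equals the closed-form G statistic", {
  d <- data.frame(y = c(10, 20), g = factor(c("a", "b")))
  full <- fit_count_model(y ~ g, d)
  null <- fit_count_model(y ~ 1, d)
  a <- anova_deviance(full, null)
  G <- 2 * (10 * log(10 / 15) + 20 * log(20 / 15))
  expect_equal(a$statistic, G, tolerance = 1e-10)
  expect_equal(a$df, 1L)

  same <- anova_deviance(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  other <- fit_count_model(y ~ 1, data.frame(y = c(1, 2, 3)))
  expect_error(anova_deviance(full, other), "different numbers")

  set.seed(20)
  d3 <- data.frame(y = rpois(20, 5), u = rnorm(20), w = rnorm(20))
  expect_error(anova_deviance(fit_count_model(y ~ u, d3),
                              fit_count_model(y ~ w, d3)), "not nested")
})

test_that("LR nesting makes the full model's likelihood at least the reduced one's", {
  set.seed(24)
  d <- data.frame(x = rnorm(60), z = rnorm(60))
  d$y <- rpois(60, exp(1 + 0.3 * d$x))
  full <- fit_count_model(y ~ x + z, d)
  red <- fit_count_model(y ~ x, d)
  expect_gte(as.numeric(logLik(full)), as.numeric(logLik(red)) - 1e-10)
})

test_that("type II and III deviance tables agree with car::Anova on Poisson fits", {
  skip_if_not_installed("car")
  set.seed(25)
  d <- data.frame(a = factor(sample(c("u", "v"), 120, TRUE)),
                  x = rnorm(120))
  d$y <- rpois(120, exp(1 + 0.4 * (d$a == "v") + 0.3 * d$x +
                          0.3 * d$x * (d$a == "v")))
  f <- fit_count_model(y ~ a * x, d)
  for (ty in c("II", "III")) {
    mine <- deviance_table(f, d, type = ty)
    ref <- car::Anova(f, type = ty, test.statistic = "LR")
    expect_equal(mine$statistic,
                 ref[mine$term, "LR Chisq"], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("backward AIC keeps a strong distance effect and sheds noise covariates", {
  set.seed(26)
  keep_distance <- 0L
  for (r in 1:25) {
    n <- 70
    d <- data.frame(distance = runif(n, 0, 100),
                    noise_a = rnorm(n),
                    noise_b = factor(sample(c("p", "q"), n, TRUE)))
    d$y <- rpois(n, exp(2 - 0.03 * d$distance))
    sel <- backward_aic(y ~ distance + noise_a + noise_b, d)
    kept <- attr(terms(sel$fit), "term.labels")
    if ("distance" %in% kept) keep_distance <- keep_distance + 1L
  }
  expect_gte(keep_distance, 24L)  # >= 95% retention

  # a single genuinely strong term is never dropped
  set.seed(27)
  d <- data.frame(x = rnorm(100))
  d$y <- rpois(100, exp(1 + 1 * d$x))
  sel <- backward_aic(y ~ x, d)
  expect_true("x" %in% attr(terms(sel$fit), "term.labels"))
})

test_that("all-noise covariates are usually stripped to the intercept", {
  set.seed(28)
  n_null <- 0L
  for (r in 1:20) {
    d <- data.frame(x = rnorm(60), z = rnorm(60))
    d$y <- rpois(60, 5)
    sel <- backward_aic(y ~ x + z, d)
    if (length(attr(terms(sel$fit), "term.labels")) == 0L)
      n_null <- n_null + 1L
  }
  expect_gt(n_null, 10L)  # plurality of replicates
})

test_that("Pearson GOF is zero for a saturated fit and calibrated for Poisson data", {
  d <- data.frame(y = c(3, 8, 15), g = factor(1:3))
  sat <- fit_count_model(y ~ g, d)
  expect_equal(pearson_gof(sat)$statistic, 0, tolerance = 1e-10)

  set.seed(29)
  ratios <- replicate(40, {
    dd <- data.frame(x = rnorm(200))
    dd$y <- rpois(200, exp(1 + 0.3 * dd$x))
    pearson_gof(fit_count_model(y ~ x, dd))$dispersion
  })
  expect_gt(mean(ratios > 0.8 & ratios < 1.2), 0.85)
})

test_that("Pearson dispersion flags a Poisson fit to overdispersed counts", {
  set.seed(30)
  flagged <- replicate(30, {
    dd <- data.frame(x = rnorm(200))
    dd$y <- rnbinom(200, mu = exp(1 + 0.3 * dd$x), size = 2)
    pearson_gof(fit_count_model(y ~ x, dd))$dispersion > 1.5
  })
  expect_gte(mean(flagged), 0.95)
})

test_that("one-way ANOVA reproduces hand computations and flags degeneracy", {
  a <- oneway_anova(list(g1 = c(1, 2, 3), g2 = c(4, 5, 6)))
  expect_equal(a$statistic, 13.5)
  expect_equal(c(a$df1, a$df2), c(1L, 4L))

  same <- oneway_anova(list(g1 = c(2, 4, 9), g2 = c(2, 4, 9)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  expect_error(oneway_anova(list(g1 = c(3, 3), g2 = c(3, 3))), "undefined")
  expect_error(oneway_anova(list(g1 = c(1, 2))), "two nonempty groups")
})

test_that("one-way ANOVA p-values are uniform under the null", {
  set.seed(31)
  p <- replicate(400, {
    y <- rnorm(24)
    oneway_anova(split(y, rep(1:3, 8)))$p.value
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("Wald contrasts match single-coefficient z statistics", {
  set.seed(32)
  d <- data.frame(x = rnorm(100))
  d$y <- rpois(100, exp(1 + 0.5 * d$x))
  f <- fit_count_model(y ~ x, d)
  w <- wald_contrast(f, c(0, 1))
  expect_equal(w$z, coef(f)[["x"]] / sqrt(vcov(f)["x", "x"]))

  z0 <- wald_contrast(f, c(0, 0))
  expect_equal(z0$z, 0)
  expect_equal(z0$p.value, 1)
  expect_error(wald_contrast(f, c(1, 0, 0)), "length")
})

test_that("a strong sex effect is detected by the Wald contrast at large n", {
  set.seed(33)
  hits <- replicate(30, {
    d <- data.frame(sex = factor(rep(c("f", "m"), each = 200)))
    d$y <- rpois(400, exp(3 + log(2) * (d$sex == "m")))
    f <- fit_count_model(y ~ sex, d)
    wald_contrast(f, c(0, 1))$p.value < 0.001
  })
  expect_gte(mean(hits), 0.99)
})
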