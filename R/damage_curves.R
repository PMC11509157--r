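#' Predict a distance-decay curve from a fitted count model
#'
#' Response-scale predictions over a grid of border distances, holding
#' all other covariates at supplied stratum values, with delta-method
#' standard errors (the log-link prediction standard error times the
#' predicted mean).
#'
#' @param fit a model from [fit_count_model()] containing the distance
#'   term.
#' @param grid numeric vector of distances (meters), inside the range the
#'   model saw; extrapolation beyond it triggers a warning.
#' @param at data.frame of the remaining covariates: either one row
#'   (recycled along the grid) or one row per grid point. Exposure
#'   columns used by an `offset()` term belong here too (e.g.
#'   `total_fruit = 1` for a per-fruit rate).
#' @param distance_var name of the distance column in the model, default
#'   `"distance_to_border"`.
#' @return data.frame with `distance`, `fit`, `se` (both on the response
#'   scale).
#' @export
predict_curve <- function(fit, grid, at = NULL,
                          distance_var = "distance_to_border") {
  vars <- all.vars(stats::formula(fit))
  if (!distance_var %in% vars)
    stop("model does not contain the distance term '", distance_var, "'")
  mf <- stats::model.frame(fit)
  if (distance_var %in% names(mf)) {
    rng <- range(mf[[distance_var]])
    if (min(grid) < rng[1L] - 1e-9 || max(grid) > rng[2L] + 1e-9)
      warning("grid extrapolates beyond the observed distance range [",
              signif(rng[1L], 4), ", ", signif(rng[2L], 4), "] m")
  }
  nd <- if (is.null(at)) data.frame(row.names = seq_along(grid)) else {
    if (nrow(at) == 1L) at[rep(1L, length(grid)), , drop = FALSE]
    else if (nrow(at) == length(grid)) at
    else stop("'at' must have 1 row or one row per grid point")
  }
  nd[[distance_var]] <- grid
  pr <- stats::predict(fit, newdata = nd, type = "link", se.fit = TRUE)
  mu <- exp(pr$fit)
  data.frame(distance = grid, fit = unname(mu),
             se = unname(pr$se.fit * mu))
}

#' Distance within which half the cumulated damage lies (d50)
#'
#' Trapezoidal cumulative integral of a nonnegative curve over its
#' distance grid, normalized by the total area; d50 is the distance at
#' which the cumulative fraction crosses 0.5, linearly interpolated
#' between grid points. For a flat curve on `[0, L]` this is exactly
#' `L/2`; for decay concentrated near the border it is much smaller.
#'
#' @param grid increasing numeric vector of distances.
#' @param values nonnegative curve values on `grid`.
#' @return d50 in meters.
#' @export
cumulated_d50 <- function(grid, values) {
  if (length(grid) != length(values) || length(grid) < 2L)
    stop("grid and values must match and have length >= 2")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be increasing")
  if (any(values < 0)) stop("curve values must be nonnegative")
  h <- diff(grid)
  cum <- c(0, cumsum(h * (values[-1L] + values[-length(values)]) / 2))
  total <- cum[length(cum)]
  if (total <= 0)
    stop("d50 undefined: the curve has zero total area")
  frac <- cum / total
  j <- which(frac >= 0.5)[1L]
  if (j == 1L) return(grid[1L])
  grid[j - 1L] + (0.5 - frac[j - 1L]) / (frac[j] - frac[j - 1L]) *
    (grid[j] - grid[j - 1L])
}

#' Control-minus-trap differential effect and its crossover distance
#'
#' Pointwise difference between the control-stratum and trap-stratum
#' fitted curves on a common grid, with the propagated standard error
#' (root sum of squared pointwise standard errors), and the crossover:
#' the distance of equal damage where the difference changes sign.
#' Negative differences (trap above control) near the border followed by
#' positive ones beyond the crossover are the signature of a border
#' damage shift. The root is located by sign-change bracketing on the
#' grid and bisection of the linear interpolant to 0.01 m; when the
#' difference never changes sign (or the curves are identical) the
#' crossover is undefined and returned as `NA`.
#'
#' @param control,trap data.frames from [predict_curve()] on the same
#'   grid (columns `distance`, `fit`, `se`).
#' @return list of class `differential_effect` with `curve` (data.frame:
#'   `distance`, `difference`, `se`) and `crossover` (meters or `NA`).
#' @export
differential_effect <- function(control, trap) {
  if (!identical(control$distance, trap$distance))
    stop("control and trap curves must share the same distance grid")
  diff_ <- control$fit - trap$fit
  se <- sqrt(control$se^2 + trap$se^2)
  crossover <- .first_sign_change_root(control$distance, diff_)
  structure(list(
    curve = data.frame(distance = control$distance, difference = diff_,
                       se = se),
    crossover = crossover), class = "differential_effect")
}

# first sign change of a gridded function, bisected to < 0.01 m
.first_sign_change_root <- function(x, y) {
  s <- sign(y)
  nz <- which(s != 0)
  if (length(nz) == 0L) return(NA_real_)
  flip <- which(s[nz[-length(nz)]] * s[nz[-1L]] < 0)
  if (length(flip) == 0L) return(NA_real_)
  i <- nz[flip[1L]]
  j <- nz[flip[1L] + 1L]
  # exact zeros on grid points between the bracketing nonzeros
  if (j > i + 1L) return(x[i + 1L])
  f <- stats::approxfun(x, y)
  lo <- x[i]; hi <- x[j]
  flo <- y[i]
  while (hi - lo > 0.005) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

#' @export
print.differential_effect <- function(x, ...) {
  cat("Differential effect (control - trap) on",
      length(x$curve$distance), "grid points\n")
  if (is.na(x$crossover)) {
    cat("Crossover: undefined (no sign change on the grid)\n")
  } else {
    cat(sprintf("Crossover (equal damage): %.2f m\n", x$crossover))
  }
  invisible(x)
}
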