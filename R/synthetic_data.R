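#' Define a synthetic orchard trial scenario
#'
#' A scenario bundles every parameter of the synthetic trial generator:
#' geometry (border length, orchard depth, alternating trap/control
#' plots, trap positions offset outside the border), the distance-decay
#' damage model per stratum, per-fruit injury severity, and the seasonal
#' trap-catch process (negative binomial totals, sex split, sail/bin
#' retention split). Defaults emulate a border mass-trapping trial on a
#' continuous apple orchard: four 200 m plots alternating trap/control
#' along an 800 m border, four pheromone traps per trap plot spaced 45 m
#' and standing 7 m outside the border, about 92 fruit scored per
#' assessment point, a steep damage decay away from the border in trap
#' plots against a weak increase in control plots, season-increasing
#' overdispersed catches totalling about 520 adults per trap with a
#' male:female ratio of 0.85 and a male-biased sail/bin split.
#'
#' @param border_length border front, meters.
#' @param depth orchard depth from border to opposite side, meters.
#' @param plot_width width of each plot along the border, meters; plots
#'   alternate trap, control, trap, ... starting with a trap plot.
#' @param n_points number of damage assessment points.
#' @param fruit_per_point_mean mean fruit scored per point.
#' @param fruit_per_point_sd between-point SD of scored fruit.
#' @param trap_positions optional matrix of trap x,y coordinates; by
#'   default four traps per trap plot, spaced 45 m, at `y = -trap_offset`.
#' @param trap_offset trap standoff outside the border, meters.
#' @param incidence_intercept_control,incidence_slope_control log-scale
#'   intercept and per-meter slope of the control-stratum per-fruit
#'   injury probability `exp(a + b d)` (clamped to `[0, 1]`).
#' @param incidence_intercept_trap,incidence_slope_trap same for the
#'   trap stratum.
#' @param incidence_sd_log SD of the lognormal point-level heterogeneity
#'   added to the log incidence (overdispersion between points).
#' @param severity_mean_injuries mean injuries per injured fruit
#'   (zero-truncated Poisson).
#' @param catch_mean_by_date named numeric vector: expected catch per
#'   trap for each assessment date (names are ISO dates).
#' @param catch_dispersion negative binomial size parameter of per-trap
#'   per-date totals.
#' @param sex_ratio_mf male:female ratio of expected catches.
#' @param male_sail_fraction,female_sail_fraction probability that a
#'   caught male (female) is retained on the sticky sail rather than in
#'   the water bin.
#' @param seed integer RNG seed; one seed yields a bit-identical trial.
#' @return list of class `orchard_scenario`.
#' @export
orchard_scenario <- function(border_length = 800,
                             depth = 100,
                             plot_width = 200,
                             n_points = 100,
                             fruit_per_point_mean = 92,
                             fruit_per_point_sd = 2,
                             trap_positions = NULL,
                             trap_offset = 7,
                             incidence_intercept_control = log(0.055),
                             incidence_slope_control = 0.01,
                             incidence_intercept_trap = log(0.45),
                             incidence_slope_trap = -0.028,
                             incidence_sd_log = 0.35,
                             severity_mean_injuries = 2,
                             catch_mean_by_date = c(
                               "2023-05-17" = 25, "2023-06-08" = 40,
                               "2023-07-14" = 70, "2023-07-26" = 105,
                               "2023-08-11" = 135, "2023-09-02" = 145),
                             catch_dispersion = 2,
                             sex_ratio_mf = 0.85,
                             male_sail_fraction = 0.689,
                             female_sail_fraction = 0.471,
                             seed = NULL) {
  sc <- list(border_length = border_length, depth = depth,
             plot_width = plot_width, n_points = n_points,
             fruit_per_point_mean = fruit_per_point_mean,
             fruit_per_point_sd = fruit_per_point_sd,
             trap_positions = trap_positions, trap_offset = trap_offset,
             incidence_intercept_control = incidence_intercept_control,
             incidence_slope_control = incidence_slope_control,
             incidence_intercept_trap = incidence_intercept_trap,
             incidence_slope_trap = incidence_slope_trap,
             incidence_sd_log = incidence_sd_log,
             severity_mean_injuries = severity_mean_injuries,
             catch_mean_by_date = catch_mean_by_date,
             catch_dispersion = catch_dispersion,
             sex_ratio_mf = sex_ratio_mf,
             male_sail_fraction = male_sail_fraction,
             female_sail_fraction = female_sail_fraction,
             seed = seed)
  validate_scenario(sc)
  if (is.null(sc$trap_positions))
    sc$trap_positions <- .default_trap_positions(sc)
  class(sc) <- "orchard_scenario"
  sc
}

validate_scenario <- function(sc) {
  if (sc$depth <= 0) stop("depth must be > 0")
  if (sc$border_length <= 0) stop("border_length must be > 0")
  if (sc$plot_width <= 0 || sc$plot_width > sc$border_length)
    stop("plot_width must be in (0, border_length]")
  if (sc$n_points < 1) stop("n_points must be positive")
  if (sc$fruit_per_point_mean <= 0) stop("fruit_per_point_mean must be > 0")
  if (sc$trap_offset < 0) stop("trap_offset must be nonnegative")
  if (sc$severity_mean_injuries < 1)
    stop("severity_mean_injuries must be >= 1 (injured fruit carry >= 1 injury)")
  if (any(sc$catch_mean_by_date < 0) || is.null(names(sc$catch_mean_by_date)))
    stop("catch_mean_by_date must be a named nonnegative vector")
  if (sc$catch_dispersion <= 0) stop("catch_dispersion must be > 0")
  if (sc$sex_ratio_mf < 0) stop("sex_ratio_mf must be nonnegative")
  for (f in c("male_sail_fraction", "female_sail_fraction"))
    if (sc[[f]] < 0 || sc[[f]] > 1) stop(f, " must be in [0, 1]")
  if (sc$incidence_sd_log < 0) stop("incidence_sd_log must be nonnegative")
  invisible(TRUE)
}

# plots alternate trap, control, ... from x = 0
.plot_table <- function(sc) {
  n_plots <- ceiling(sc$border_length / sc$plot_width)
  data.frame(
    plot_id = paste0("P", seq_len(n_plots)),
    x_min = (seq_len(n_plots) - 1L) * sc$plot_width,
    x_max = pmin(seq_len(n_plots) * sc$plot_width, sc$border_length),
    has_traps = rep(c(TRUE, FALSE), length.out = n_plots)
  )
}

.default_trap_positions <- function(sc) {
  pl <- .plot_table(sc)
  pl <- pl[pl$has_traps, , drop = FALSE]
  pos <- do.call(rbind, lapply(seq_len(nrow(pl)), function(i) {
    w <- pl$x_max[i] - pl$x_min[i]
    n_tr <- max(1L, floor(w / 50))  # traps spaced ~45 m within the plot
    xs <- pl$x_min[i] + (w - (n_tr - 1L) * 45) / 2 + (seq_len(n_tr) - 1L) * 45
    cbind(x = xs, y = -sc$trap_offset)
  }))
  pos
}

#' Default border polyline of a scenario
#'
#' A straight border along `y = 0` discretised into 28 recorded vertices,
#' mimicking a GNSS-surveyed orchard border.
#'
#' @param scenario an [orchard_scenario()].
#' @param n_vertices number of recorded border vertices.
#' @return A [border_polyline()].
#' @export
scenario_border <- function(scenario, n_vertices = 28L) {
  border_polyline(cbind(
    x = seq(0, scenario$border_length, length.out = n_vertices), y = 0))
}

# mean -> lambda of a zero-truncated Poisson: m = lambda / (1 - exp(-lambda))
.ztpois_lambda <- function(m) {
  if (m <= 1) return(1e-8)
  stats::uniroot(function(l) l / (1 - exp(-l)) - m,
                 lower = 1e-8, upper = m + 10)$root
}

# draw n zero-truncated Poisson counts by redrawing zeros
.rztpois <- function(n, lambda) {
  x <- stats::rpois(n, lambda)
  while (any(x == 0)) {
    z <- x == 0
    x[z] <- stats::rpois(sum(z), lambda)
  }
  x
}

#' Generate damage assessment points
#'
#' Lays assessment points on a jittered grid of tree rows (4 m row
#' spacing) across the orchard, draws per-point fruit totals around the
#' scenario mean, injures fruit binomially with the stratum's clamped
#' log-linear distance-decay probability (times a lognormal point-level
#' heterogeneity factor), and distributes injured fruit over classes 2-6
#' by binning a zero-truncated Poisson injury count per injured fruit.
#' Class counts always sum to the point's fruit total.
#'
#' @param scenario an [orchard_scenario()]; if it carries a seed, the
#'   RNG is seeded so repeated calls are identical.
#' @param scheme the [damage_class_scheme()] used for binning.
#' @return data.frame: `id, x, y, plot_id, has_traps, management,
#'   variety, n_class1..n_class6`.
#' @export
generate_assessment_points <- function(scenario,
                                       scheme = damage_class_scheme()) {
  validate_scenario(scenario)
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  sc <- scenario
  n <- sc$n_points
  rows_y <- seq(2, max(2, sc$depth - 2), by = 4)
  y <- rows_y[(seq_len(n) - 1L) %% length(rows_y) + 1L] +
    stats::runif(n, -0.5, 0.5)
  y <- pmin(pmax(y, 0.5), sc$depth - 0.5)
  x <- (seq_len(n) - 0.5) / n * sc$border_length + stats::runif(n, -1.5, 1.5)
  x <- pmin(pmax(x, 0), sc$border_length)

  pl <- .plot_table(sc)
  pi <- findInterval(x, pl$x_min)
  plot_id <- pl$plot_id[pi]
  has_traps <- pl$has_traps[pi]

  # management and variety assigned per 100 m parcel strip
  parcel <- floor(x / 100)
  parcels <- sort(unique(parcel))
  mgmt_by_parcel <- sample(c("organic", "IPM"), length(parcels), replace = TRUE)
  var_by_parcel <- sample(c("Gala", "Kanzi", "RosyGlow", "GrannySmith"),
                          length(parcels), replace = TRUE)
  management <- mgmt_by_parcel[match(parcel, parcels)]
  variety <- var_by_parcel[match(parcel, parcels)]

  total <- pmax(1L, round(stats::rnorm(n, sc$fruit_per_point_mean,
                                       sc$fruit_per_point_sd)))
  border <- scenario_border(sc)
  d <- min_distance_to_border(cbind(x, y), border)
  a <- ifelse(has_traps, sc$incidence_intercept_trap,
              sc$incidence_intercept_control)
  b <- ifelse(has_traps, sc$incidence_slope_trap, sc$incidence_slope_control)
  eta <- a + b * d + stats::rnorm(n, 0, sc$incidence_sd_log)
  p <- pmin(pmax(exp(eta), 0), 1)
  injured <- stats::rbinom(n, total, p)

  lambda <- .ztpois_lambda(sc$severity_mean_injuries)
  top <- max(scheme$injury_max)
  counts <- matrix(0L, n, nrow(scheme))
  for (i in seq_len(n)) {
    counts[i, 1L] <- total[i] - injured[i]
    if (injured[i] > 0) {
      inj <- pmin(.rztpois(injured[i], lambda), top)
      cl <- assign_class(inj, scheme)
      tab <- tabulate(cl, nbins = nrow(scheme))
      counts[i, ] <- counts[i, ] + tab
    }
  }
  colnames(counts) <- paste0("n_class", scheme$class)
  data.frame(id = seq_len(n), x = x, y = y, plot_id = plot_id,
             has_traps = has_traps, management = management,
             variety = variety, counts)
}

#' Generate seasonal trap catches
#'
#' For each trap and assessment date, draws a negative binomial total
#' around the date's expected catch, splits it male/female binomially by
#' the scenario sex ratio, and assigns each insect to the sticky sail or
#' the water bin by the sex-specific sail fraction.
#'
#' @param scenario an [orchard_scenario()]; a carried seed makes repeated
#'   calls identical.
#' @param dates date labels; default the names of
#'   `scenario$catch_mean_by_date`. If supplied, their number must match
#'   the catch means.
#' @return data.frame in long format: `trap_id, x, y, date, sex, part,
#'   count` (four rows per trap-date).
#' @export
generate_trap_catches <- function(scenario, dates = NULL) {
  validate_scenario(scenario)
  sc <- scenario
  means <- sc$catch_mean_by_date
  if (is.null(dates)) dates <- names(means)
  if (length(dates) < 1L) stop("need at least one assessment date")
  if (length(dates) != length(means))
    stop("dates and catch_mean_by_date lengths differ")
  traps <- sc$trap_positions
  if (is.null(traps) || nrow(traps) < 1L) stop("need at least one trap")
  if (!is.null(sc$seed)) set.seed(sc$seed + 1L)

  p_male <- sc$sex_ratio_mf / (1 + sc$sex_ratio_mf)
  out <- vector("list", nrow(traps) * length(dates))
  k <- 0L
  for (tr in seq_len(nrow(traps))) {
    for (j in seq_along(dates)) {
      tot <- stats::rnbinom(1L, mu = means[j], size = sc$catch_dispersion)
      males <- stats::rbinom(1L, tot, p_male)
      females <- tot - males
      m_sail <- stats::rbinom(1L, males, sc$male_sail_fraction)
      f_sail <- stats::rbinom(1L, females, sc$female_sail_fraction)
      k <- k + 1L
      out[[k]] <- data.frame(
        trap_id = paste0("T", tr),
        x = unname(traps[tr, 1L]), y = unname(traps[tr, 2L]),
        date = unname(dates[j]),
        sex = rep(c("male", "male", "female", "female")),
        part = rep(c("sail", "bin"), 2L),
        count = c(m_sail, males - m_sail, f_sail, females - f_sail))
    }
  }
  do.call(rbind, out)
}

#' Generate a full synthetic trial
#'
#' Seeds the RNG once from the scenario and produces every input the
#' analysis pipeline consumes: assessment points, trap catches, trap
#' positions, border polyline and the damage class scheme.
#'
#' @param scenario an [orchard_scenario()].
#' @param scheme the [damage_class_scheme()].
#' @return list of class `trial_bundle` with elements `points`,
#'   `catches`, `traps` (data.frame `trap_id, x, y`), `border`, `scheme`,
#'   `scenario`.
#' @export
generate_trial <- function(scenario, scheme = damage_class_scheme()) {
  points <- generate_assessment_points(scenario, scheme)
  catches <- generate_trap_catches(scenario)
  traps <- unique(catches[, c("trap_id", "x", "y")])
  rownames(traps) <- NULL
  structure(list(points = points, catches = catches, traps = traps,
                 border = scenario_border(scenario), scheme = scheme,
                 scenario = scenario),
            class = "trial_bundle")
}

#' @export
print.trial_bundle <- function(x, ...) {
  cat("Synthetic orchard trial:", nrow(x$points), "assessment points,",
      nrow(x$traps), "traps,", length(unique(x$catches$date)),
      "assessment dates\n")
  invisible(x)
}
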