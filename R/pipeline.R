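#' Summarise seasonal trap catches
#'
#' Per-trap season totals with their mean and SD (n-1 denominator),
#' totals and per-trap means by sex with the resulting male:female
#' ratio, the sail/bin percentage split by sex (mean and SD over traps),
#' and per-date totals.
#'
#' @param catches long catch table (`trap_id, date, sex, part, count`),
#'   as from [generate_trap_catches()] or [read_traps_csv()].
#' @return list of class `catch_summary`: `per_trap`, `overall`
#'   (mean/sd/total), `by_sex`, `sex_ratio_mf`, `sail_split`, `by_date`.
#' @export
summarize_catches <- function(catches) {
  stopifnot(all(c("trap_id", "date", "sex", "part", "count") %in%
                  names(catches)))
  if (nrow(catches) == 0L) stop("need at least one trap record")
  per_trap <- stats::aggregate(count ~ trap_id, catches, sum)
  overall <- list(mean = mean(per_trap$count),
                  sd = stats::sd(per_trap$count),
                  total = sum(per_trap$count),
                  n_traps = nrow(per_trap))
  by_sex <- stats::aggregate(count ~ sex, catches, sum)
  per_trap_sex <- stats::aggregate(count ~ trap_id + sex, catches, sum)
  mean_by_sex <- stats::aggregate(count ~ sex, per_trap_sex, mean)
  m <- mean_by_sex$count[mean_by_sex$sex == "male"]
  f <- mean_by_sex$count[mean_by_sex$sex == "female"]
  sex_ratio <- if (length(m) && length(f) && f > 0) m / f else NA_real_

  # sail percentage per trap and sex, then mean +- sd across traps
  tps <- stats::aggregate(count ~ trap_id + sex + part, catches, sum)
  wide <- stats::reshape(tps, idvar = c("trap_id", "sex"),
                         timevar = "part", direction = "wide")
  sail_col <- wide[["count.sail"]] %||% 0
  bin_col <- wide[["count.bin"]] %||% 0
  tot <- sail_col + bin_col
  wide$pct_sail <- ifelse(tot > 0, 100 * sail_col / tot, NA_real_)
  sail_split <- do.call(rbind, lapply(split(wide, wide$sex), function(w)
    data.frame(sex = w$sex[1L],
               pct_sail_mean = mean(w$pct_sail, na.rm = TRUE),
               pct_sail_sd = stats::sd(w$pct_sail, na.rm = TRUE))))
  rownames(sail_split) <- NULL
  by_date <- stats::aggregate(count ~ date, catches, sum)
  structure(list(per_trap = per_trap, overall = overall, by_sex = by_sex,
                 mean_per_trap_by_sex = mean_by_sex,
                 sex_ratio_mf = sex_ratio, sail_split = sail_split,
                 by_date = by_date),
            class = "catch_summary")
}

#' @export
print.catch_summary <- function(x, ...) {
  cat(sprintf("Catches: %d adults over %d traps; per-trap %.2f +/- %.2f\n",
              x$overall$total, x$overall$n_traps, x$overall$mean,
              x$overall$sd))
  cat(sprintf("Sex ratio (m:f of per-trap means): %.2f:1\n", x$sex_ratio_mf))
  for (i in seq_len(nrow(x$sail_split)))
    cat(sprintf("  %s on sail: %.2f%% +/- %.2f\n", x$sail_split$sex[i],
                x$sail_split$pct_sail_mean[i], x$sail_split$pct_sail_sd[i]))
  invisible(x)
}

#' Per-point damage and spatial metrics
#'
#' Joins the damage metrics (incidence, severity, injured count, fruit
#' total) with the spatial covariates (minimum distance to the border
#' polyline, distance to the nearest trap, catch index) onto the
#' assessment-point table.
#'
#' @param points assessment-point table (columns `id, x, y, plot_id,
#'   has_traps, management, variety, n_class1..`).
#' @param border a [border_polyline()].
#' @param traps data.frame `trap_id, x, y` of trap positions.
#' @param trap_totals named numeric vector of season-total catches per
#'   trap (names = `trap_id`), in the order of `traps`.
#' @param scheme the [damage_class_scheme()].
#' @param catch_index_variant `"displayed"` or `"text"`.
#' @return `points` with columns `total_fruit, injured, incidence,
#'   severity, distance_to_border, distance_to_nearest_trap, catch_index`
#'   appended.
#' @export
point_metrics <- function(points, border, traps, trap_totals,
                          scheme = damage_class_scheme(),
                          catch_index_variant = c("displayed", "text")) {
  catch_index_variant <- match.arg(catch_index_variant)
  cc <- as.matrix(points[, paste0("n_class", scheme$class)])
  points$total_fruit <- rowSums(cc)
  points$injured <- points$total_fruit - cc[, 1L]
  points$incidence <- damage_incidence(cc, scheme)
  points$severity <- damage_severity(cc, scheme)
  points$distance_to_border <-
    min_distance_to_border(as.matrix(points[, c("x", "y")]), border)
  dm <- distance_matrix(as.matrix(points[, c("x", "y")]),
                        as.matrix(traps[, c("x", "y")]))
  points$distance_to_nearest_trap <- nearest_trap_distance(dm)
  h <- trap_totals[traps$trap_id]
  points$catch_index <- catch_index(unname(h), dm,
                                    variant = catch_index_variant)
  points
}

.modal <- function(x) names(sort(table(x), decreasing = TRUE))[1L]

# stratum covariate profile used for curve prediction: modal factor
# levels and median continuous covariates within the stratum
.stratum_profile <- function(metrics, stratum_has_traps) {
  s <- metrics[metrics$has_traps == stratum_has_traps, , drop = FALSE]
  if (nrow(s) == 0L) s <- metrics
  data.frame(
    has_traps = stratum_has_traps,
    management = .modal(s$management),
    variety = .modal(s$variety),
    catch_index = stats::median(s$catch_index),
    distance_to_nearest_trap = stats::median(s$distance_to_nearest_trap),
    total_fruit = 1)
}

# drop formula terms that cannot be estimated on this data (single-level
# factors, constant columns)
.estimable_terms <- function(terms, data) {
  ok <- vapply(terms, function(t) {
    vars <- all.vars(stats::reformulate(t))
    all(vapply(vars, function(v) length(unique(data[[v]])) > 1L, logical(1L)))
  }, logical(1L))
  terms[ok]
}

# prune terms whose columns are aliased with earlier ones (e.g. parcel-
# constant covariates confounded with each other), highest-order first,
# until the design is full rank
.prune_aliased <- function(formula, data) {
  repeat {
    X <- stats::model.matrix(formula, stats::model.frame(formula, data))
    q <- qr(X)
    if (q$rank == ncol(X)) return(formula)
    bad_cols <- q$pivot[(q$rank + 1L):ncol(X)]
    asgn <- attr(X, "assign")[bad_cols]
    tl <- attr(stats::terms(formula), "term.labels")
    bad_terms <- unique(tl[asgn[asgn > 0L]])
    # drop the most complex offending term first, keep its marginals
    ord <- attr(stats::terms(formula), "order")[match(bad_terms, tl)]
    victim <- bad_terms[which.max(ord)]
    formula <- .drop_term(formula, victim, also_containing = TRUE)
  }
}

#' Run the full border-trapping analysis pipeline
#'
#' Executes every stage on a trial bundle: catch summary and catch
#' model, per-point damage/spatial metrics, backward-AIC negative
#' binomial models for damage incidence (injured-fruit counts with a
#' log fruit-total offset) and severity (per-point severity rounded to
#' the nearest integer; the unrounded value stays in the metrics table),
#' type III analysis-of-deviance tables and Pearson goodness of fit,
#' fitted distance-decay curves per stratum with their 50%-cumulated
#' distances, and the control-minus-trap differential effect with its
#' crossover. Stage progress is logged to stderr; when the trial has no
#' trap plots (or no control plots) the differential stage is skipped
#' with a logged reason.
#'
#' @param bundle a `trial_bundle` (from [generate_trial()] or
#'   [read_trial()]).
#' @param out_dir optional directory; when given, writes
#'   `catch_summary.csv`, `point_metrics.csv`, `model_incidence.json`,
#'   `model_severity.json`, `curves_incidence.csv`,
#'   `curves_severity.csv` and `summary.json`.
#' @param catch_index_variant `"displayed"` or `"text"`.
#' @param grid_step curve grid step, meters.
#' @param select run backward AIC term selection (default) or keep the
#'   full model.
#' @return list of class `trial_report`.
#' @export
run_pipeline <- function(bundle, out_dir = NULL,
                         catch_index_variant = c("displayed", "text"),
                         grid_step = 0.5, select = TRUE) {
  catch_index_variant <- match.arg(catch_index_variant)
  stopifnot(inherits(bundle, "trial_bundle"))
  log_stage <- function(...) message("[", ..1, "] ",
                                     paste(c(...)[-1L], collapse = " "))

  log_stage("catches", "summarising trap catches")
  csum <- summarize_catches(bundle$catches)
  catch_fit <- tryCatch({
    cd <- stats::aggregate(count ~ trap_id + date + sex + part,
                           bundle$catches, sum)
    cd$date <- factor(cd$date)
    suppressWarnings(fit_count_model(count ~ sex * part + date, cd,
                                     "negative_binomial"))
  }, error = function(e) {
    log_stage("catches", "catch model failed:", conditionMessage(e)); NULL
  })
  sex_in_bin <- if (!is.null(catch_fit)) {
    cn <- names(stats::coef(catch_fit))
    ctr <- as.numeric(cn == "sexmale")  # male - female within the bin
    wald_contrast(catch_fit, ctr)
  } else NULL

  log_stage("metrics", "computing per-point damage and spatial metrics")
  metrics <- point_metrics(bundle$points, bundle$border, bundle$traps,
                           trap_totals = stats::setNames(
                             csum$per_trap$count, csum$per_trap$trap_id),
                           scheme = bundle$scheme,
                           catch_index_variant = catch_index_variant)

  log_stage("models", "fitting damage incidence model")
  both_strata <- length(unique(metrics$has_traps)) > 1L
  base_terms <- c("catch_index", "distance_to_nearest_trap", "variety",
                  if (both_strata) c("has_traps * management",
                                     "has_traps * distance_to_border")
                  else c("management", "distance_to_border"))
  inc_terms <- .estimable_terms(base_terms, metrics)
  inc_form <- stats::reformulate(
    c(inc_terms, "offset(log(total_fruit))"), response = "injured")
  inc_form <- .prune_aliased(inc_form, metrics)
  inc <- if (select) suppressWarnings(
    backward_aic(inc_form, metrics, "negative_binomial"))
  else list(fit = suppressWarnings(
    fit_count_model(inc_form, metrics, "negative_binomial")),
    dropped = character())
  inc_dev <- tryCatch(
    suppressWarnings(deviance_table(inc$fit, metrics, type = "III")),
    error = function(e) NULL)

  log_stage("models", "fitting damage severity model")
  sev_data <- metrics[!is.na(metrics$severity), , drop = FALSE]
  sev_data$severity_round <- pmax(1L, as.integer(round(sev_data$severity)))
  sev_terms <- .estimable_terms(base_terms, sev_data)
  sev_form <- .prune_aliased(
    stats::reformulate(sev_terms, response = "severity_round"), sev_data)
  sev <- tryCatch({
    if (select) suppressWarnings(
      backward_aic(sev_form, sev_data, "negative_binomial"))
    else list(fit = suppressWarnings(
      fit_count_model(sev_form, sev_data, "negative_binomial")),
      dropped = character())
  }, error = function(e) {
    log_stage("models", "severity model failed:", conditionMessage(e)); NULL
  })

  log_stage("curves", "building distance-decay curves")
  grid <- seq(0, max(metrics$distance_to_border), by = grid_step)
  curves <- .stratum_curves(inc$fit, metrics, grid, scale = 100)
  sev_curves <- if (!is.null(sev) &&
                    "distance_to_border" %in% all.vars(stats::formula(sev$fit)))
    .stratum_curves(sev$fit, sev_data, grid, scale = 1) else NULL

  diff_inc <- NULL
  d50 <- list()
  if (both_strata && !is.null(curves)) {
    d50$incidence_control <- tryCatch(
      cumulated_d50(grid, curves$control$fit), error = function(e) NA_real_)
    d50$incidence_trap <- tryCatch(
      cumulated_d50(grid, curves$trap$fit), error = function(e) NA_real_)
    diff_inc <- differential_effect(curves$control, curves$trap)
  } else {
    log_stage("curves",
              "differential-effect stage skipped: need both trap and control strata")
  }
  diff_sev <- NULL
  if (both_strata && !is.null(sev_curves)) {
    d50$severity_control <- tryCatch(
      cumulated_d50(grid, sev_curves$control$fit), error = function(e) NA_real_)
    d50$severity_trap <- tryCatch(
      cumulated_d50(grid, sev_curves$trap$fit), error = function(e) NA_real_)
    diff_sev <- differential_effect(sev_curves$control, sev_curves$trap)
  }

  report <- structure(list(
    catch_summary = csum, catch_fit = catch_fit, sex_in_bin = sex_in_bin,
    metrics = metrics,
    incidence = inc, incidence_deviance = inc_dev, severity = sev,
    curves_incidence = curves, curves_severity = sev_curves,
    d50 = d50, differential_incidence = diff_inc,
    differential_severity = diff_sev,
    grid = grid, catch_index_variant = catch_index_variant,
    scenario = bundle$scenario), class = "trial_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# predict incidence/severity curves for the trap and control strata
.stratum_curves <- function(fit, metrics, grid, scale = 1) {
  if (!"distance_to_border" %in% all.vars(stats::formula(fit))) return(NULL)
  curves <- lapply(c(control = FALSE, trap = TRUE), function(ht) {
    prof <- .stratum_profile(metrics, ht)
    cv <- suppressWarnings(predict_curve(fit, grid, at = prof))
    cv$fit <- cv$fit * scale
    cv$se <- cv$se * scale
    cv
  })
  curves
}

#' Headline numbers of a trial report
#'
#' @param report a `trial_report` from [run_pipeline()].
#' @return Named list of scalar summaries (means, d50s, crossovers).
#' @export
report_summary <- function(report) {
  m <- report$metrics
  ctl <- m$has_traps == FALSE
  list(
    n_points = nrow(m),
    n_traps = report$catch_summary$overall$n_traps,
    mean_catch_per_trap = report$catch_summary$overall$mean,
    sd_catch_per_trap = report$catch_summary$overall$sd,
    sex_ratio_mf = report$catch_summary$sex_ratio_mf,
    incidence_control_pct = if (any(ctl)) mean(m$incidence[ctl]) else NA,
    incidence_trap_pct = if (any(!ctl)) mean(m$incidence[!ctl]) else NA,
    severity_control = if (any(ctl)) mean(m$severity[ctl], na.rm = TRUE)
    else NA,
    severity_trap = if (any(!ctl)) mean(m$severity[!ctl], na.rm = TRUE)
    else NA,
    d50 = report$d50,
    crossover_incidence_m = if (!is.null(report$differential_incidence))
      report$differential_incidence$crossover else NA,
    crossover_severity_m = if (!is.null(report$differential_severity))
      report$differential_severity$crossover else NA)
}

#' Write a trial report to disk
#'
#' @param report a `trial_report`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                       row.names = FALSE)
  w(report$catch_summary$per_trap, "catch_summary.csv")
  w(report$metrics, "point_metrics.csv")
  jsonlite::write_json(count_fit_summary(report$incidence$fit),
                       file.path(out_dir, "model_incidence.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  if (!is.null(report$severity))
    jsonlite::write_json(count_fit_summary(report$severity$fit),
                         file.path(out_dir, "model_severity.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  if (!is.null(report$curves_incidence)) {
    ci <- cbind(report$curves_incidence$control,
                trap_fit = report$curves_incidence$trap$fit,
                trap_se = report$curves_incidence$trap$se)
    names(ci)[2:3] <- c("control_fit", "control_se")
    w(ci, "curves_incidence.csv")
  }
  if (!is.null(report$curves_severity)) {
    cs <- cbind(report$curves_severity$control,
                trap_fit = report$curves_severity$trap$fit,
                trap_se = report$curves_severity$trap$se)
    names(cs)[2:3] <- c("control_fit", "control_se")
    w(cs, "curves_severity.csv")
  }
  jsonlite::write_json(report_summary(report),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}

#' @export
print.trial_report <- function(x, ...) {
  s <- report_summary(x)
  cat(sprintf("Trial report: %d points, %d traps\n", s$n_points, s$n_traps))
  cat(sprintf("  mean catch per trap %.2f +/- %.2f, sex ratio %.2f:1\n",
              s$mean_catch_per_trap, s$sd_catch_per_trap, s$sex_ratio_mf))
  if (!is.na(s$incidence_control_pct))
    cat(sprintf("  incidence: control %.2f%%, trap %.2f%%\n",
                s$incidence_control_pct, s$incidence_trap_pct))
  if (length(x$d50))
    cat(sprintf("  d50 incidence: control %.1f m, trap %.1f m\n",
                x$d50$incidence_control, x$d50$incidence_trap))
  if (!is.null(x$differential_incidence))
    print(x$differential_incidence)
  invisible(x)
}
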