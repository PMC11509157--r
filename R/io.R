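#' Read and write the trial CSV and GeoJSON dialects
#'
#' The pipeline exchanges three plain-text inputs: an assessment-point
#' CSV (`id,x,y,plot_id,has_traps,management,variety,n_class1..n_class6`),
#' a long trap-catch CSV (`trap_id,x,y,date,sex,part,count`), and a
#' GeoJSON FeatureCollection carrying the border as a LineString and the
#' traps as Points. All files are UTF-8 with a header row and "."
#' decimals. Coordinates are planar meters unless `lonlat = TRUE`, in
#' which case they are projected with [lonlat_to_local()].
#'
#' @name trial_io
NULL

#' @rdname trial_io
#' @param points assessment-point table.
#' @param path file path.
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname trial_io
#' @export
read_points_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "plot_id", "has_traps", "management", "variety")
  if (!all(need %in% names(d)))
    stop("points CSV missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  if (!any(grepl("^n_class", names(d))))
    stop("points CSV needs n_class1..n_classK columns")
  d$has_traps <- as.logical(d$has_traps)
  d
}

#' @rdname trial_io
#' @param catches long catch table.
#' @export
write_traps_csv <- function(catches, path) {
  utils::write.csv(catches, path, row.names = FALSE)
  invisible(path)
}

#' @rdname trial_io
#' @export
read_traps_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trap_id", "x", "y", "date", "sex", "part", "count")
  if (!all(need %in% names(d)))
    stop("traps CSV missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  if (any(d$count < 0)) stop("catch counts must be nonnegative")
  d
}

#' @rdname trial_io
#' @param border a [border_polyline()].
#' @param traps data.frame `trap_id, x, y`.
#' @export
write_border_geojson <- function(border, traps, path) {
  features <- list(list(
    type = "Feature",
    properties = list(role = "border"),
    geometry = list(type = "LineString",
                    coordinates = lapply(seq_len(nrow(border)), function(i)
                      c(border[i, 1L], border[i, 2L])))))
  for (i in seq_len(nrow(traps))) {
    features[[length(features) + 1L]] <- list(
      type = "Feature",
      properties = list(role = "trap", trap_id = traps$trap_id[i]),
      geometry = list(type = "Point",
                      coordinates = c(traps$x[i], traps$y[i])))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' @rdname trial_io
#' @param lonlat set `TRUE` when coordinates are longitude/latitude
#'   degrees; they are then projected to local planar meters about the
#'   border centroid.
#' @export
read_border_geojson <- function(path, lonlat = FALSE) {
  g <- jsonlite::read_json(path)
  if (!identical(g$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  border <- NULL
  traps <- list()
  for (f in g$features) {
    geom <- f$geometry
    if (identical(geom$type, "LineString")) {
      border <- do.call(rbind, lapply(geom$coordinates, function(c2)
        c(as.numeric(c2[[1L]]), as.numeric(c2[[2L]]))))
    } else if (identical(geom$type, "Point")) {
      traps[[length(traps) + 1L]] <- data.frame(
        trap_id = f$properties$trap_id %||% paste0("T", length(traps) + 1L),
        x = as.numeric(geom$coordinates[[1L]]),
        y = as.numeric(geom$coordinates[[2L]]))
    }
  }
  if (is.null(border)) stop("no LineString border feature found")
  traps <- if (length(traps)) do.call(rbind, traps) else
    data.frame(trap_id = character(), x = numeric(), y = numeric())
  if (lonlat) {
    center <- colMeans(border)
    border <- lonlat_to_local(border, center)
    if (nrow(traps))
      traps[, c("x", "y")] <- lonlat_to_local(as.matrix(traps[, c("x", "y")]),
                                              center)
  }
  list(border = border_polyline(border), traps = traps)
}

#' Write or read a scenario as a flat YAML config
#'
#' Every scenario parameter is stored under its own key; vector-valued
#' parameters (per-date catch means, trap positions) keep their names or
#' columns. Reading reconstructs a validated [orchard_scenario()].
#'
#' @param scenario an [orchard_scenario()].
#' @param path YAML file path.
#' @export
write_scenario_yaml <- function(scenario, path) {
  x <- unclass(scenario)
  if (!is.null(x$trap_positions))
    x$trap_positions <- list(x = unname(x$trap_positions[, 1L]),
                             y = unname(x$trap_positions[, 2L]))
  x$catch_mean_by_date <- as.list(x$catch_mean_by_date)  # keep date keys
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$trap_positions))
    x$trap_positions <- cbind(x = as.numeric(x$trap_positions$x),
                              y = as.numeric(x$trap_positions$y))
  if (!is.null(x$catch_mean_by_date))
    x$catch_mean_by_date <- unlist(x$catch_mean_by_date)
  do.call(orchard_scenario, x)
}

#' Assemble or read a trial bundle from files
#'
#' @param points_csv,traps_csv,border_geojson paths to the three trial
#'   inputs.
#' @param scheme the [damage_class_scheme()].
#' @param lonlat whether file coordinates are lon/lat degrees.
#' @return a `trial_bundle`.
#' @export
read_trial <- function(points_csv, traps_csv, border_geojson,
                       scheme = damage_class_scheme(), lonlat = FALSE) {
  points <- read_points_csv(points_csv)
  catches <- read_traps_csv(traps_csv)
  geo <- read_border_geojson(border_geojson, lonlat = lonlat)
  traps <- unique(catches[, c("trap_id", "x", "y")])
  rownames(traps) <- NULL
  if (lonlat) {
    # project points and trap records with the border's own origin
    raw <- jsonlite::read_json(border_geojson)
    ls <- Filter(function(f) identical(f$geometry$type, "LineString"),
                 raw$features)[[1L]]
    bm <- do.call(rbind, lapply(ls$geometry$coordinates, function(c2)
      c(as.numeric(c2[[1L]]), as.numeric(c2[[2L]]))))
    center <- colMeans(bm)
    points[, c("x", "y")] <-
      lonlat_to_local(as.matrix(points[, c("x", "y")]), center)
    traps[, c("x", "y")] <-
      lonlat_to_local(as.matrix(traps[, c("x", "y")]), center)
  }
  structure(list(points = points, catches = catches, traps = traps,
                 border = geo$border, scheme = scheme, scenario = NULL),
            class = "trial_bundle")
}

#' Write every input of a trial bundle
#'
#' @param bundle a `trial_bundle`.
#' @param out_dir directory for `points.csv`, `traps.csv`,
#'   `border.geojson` and (when the bundle has a scenario)
#'   `scenario.yaml`.
#' @export
write_trial <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_points_csv(bundle$points, file.path(out_dir, "points.csv"))
  write_traps_csv(bundle$catches, file.path(out_dir, "traps.csv"))
  write_border_geojson(bundle$border, bundle$traps,
                       file.path(out_dir, "border.geojson"))
  if (!is.null(bundle$scenario))
    write_scenario_yaml(bundle$scenario, file.path(out_dir, "scenario.yaml"))
  invisible(out_dir)
}
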