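#' Border polyline
#'
#' Orchard borders are represented as planar polylines (ordered vertices,
#' meters). The field workflow records border vertices with a GNSS device
#' and interpolates a line through them; here the polyline is the line.
#'
#' @param vertices two-column matrix (or data.frame) of x,y coordinates in
#'   meters; at least two vertices, consecutive vertices distinct.
#' @return A `border_polyline` object (numeric matrix).
#' @export
border_polyline <- function(vertices) {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L || nrow(v) < 2L)
    stop("a border polyline needs a numeric n x 2 matrix with n >= 2")
  if (any(is.na(v))) stop("border vertices must be non-missing")
  seg <- diff(v)
  if (any(rowSums(seg^2) == 0))
    stop("consecutive border vertices must be distinct")
  structure(v, class = c("border_polyline", class(v)))
}

#' Minimum distance from points to a border polyline
#'
#' Exact minimum Euclidean point-to-segment distance over all segments of
#' the polyline (the perpendicular foot where it falls inside a segment,
#' the nearer endpoint otherwise).
#'
#' @param points two-column matrix (or a length-2 vector for a single
#'   point) of planar coordinates, meters.
#' @param border a [border_polyline()].
#' @return Numeric vector of distances (meters), one per point; zero iff
#'   the point lies on the polyline.
#' @examples
#' b <- border_polyline(rbind(c(0, 0), c(10, 0)))
#' min_distance_to_border(rbind(c(5, 7), c(-3, 4)), b)
#' @export
min_distance_to_border <- function(points, border) {
  if (!inherits(border, "border_polyline")) border <- border_polyline(border)
  p <- if (is.null(dim(points))) matrix(points, nrow = 1L) else as.matrix(points)
  stopifnot(ncol(p) == 2L)
  a <- border[-nrow(border), , drop = FALSE]
  d <- diff(unclass(border))
  len2 <- rowSums(d^2)
  best <- rep(Inf, nrow(p))
  for (s in seq_len(nrow(a))) {
    t <- ((p[, 1L] - a[s, 1L]) * d[s, 1L] + (p[, 2L] - a[s, 2L]) * d[s, 2L]) / len2[s]
    t <- pmin(pmax(t, 0), 1)
    dx <- p[, 1L] - (a[s, 1L] + t * d[s, 1L])
    dy <- p[, 2L] - (a[s, 2L] + t * d[s, 2L])
    best <- pmin(best, dx * dx + dy * dy)
  }
  sqrt(best)
}

#' Point-to-trap Euclidean distance matrix
#'
#' @param points two-column matrix of assessment-point coordinates.
#' @param traps two-column matrix of trap coordinates.
#' @return Matrix of meters, entry `(i, x)` = distance from point `i` to
#'   trap `x`.
#' @export
distance_matrix <- function(points, traps) {
  p <- if (is.null(dim(points))) matrix(points, nrow = 1L) else as.matrix(points)
  tr <- if (is.null(dim(traps))) matrix(traps, nrow = 1L) else as.matrix(traps)
  if (nrow(p) == 0L || nrow(tr) == 0L) stop("points and traps must be nonempty")
  dx <- outer(p[, 1L], tr[, 1L], "-")
  dy <- outer(p[, 2L], tr[, 2L], "-")
  sqrt(dx^2 + dy^2)
}

#' Nearest-trap distance per assessment point
#'
#' @param dmat a [distance_matrix()] (points x traps).
#' @return Numeric vector: each point's distance to its nearest trap.
#' @export
nearest_trap_distance <- function(dmat) apply(dmat, 1L, min)

#' Distance-weighted trap catch index
#'
#' Summarises the weighted contribution of all traps to one assessment
#' point from season-total catches `H_x` and point-to-trap distances
#' `d_xi`. Two variants exist because the index has two published
#' readings: the displayed equation, `sum_x H_x / d_xi^2`, and the prose
#' description ("square root of the sum of the squared catch/distance
#' ratios"), `sqrt(sum_x (H_x / d_xi)^2)`. The displayed equation is the
#' default; both are monotone increasing in any catch and decreasing in
#' any distance.
#'
#' @param catches numeric vector of per-trap season-total catches `H_x`.
#' @param distances matrix of meters (points x traps, as from
#'   [distance_matrix()]), or a vector of per-trap distances for a single
#'   point. All distances must be strictly positive (traps stand off the
#'   trees by design; the index is undefined at a trap).
#' @param variant `"displayed"` (default) or `"text"`.
#' @return Numeric vector, one index per point.
#' @examples
#' catch_index(c(50, 50), c(10, 20))                    # 0.625
#' catch_index(c(50, 50), c(10, 20), variant = "text")  # 5.5902
#' @export
catch_index <- function(catches, distances,
                        variant = c("displayed", "text")) {
  variant <- match.arg(variant)
  d <- if (is.null(dim(distances))) matrix(distances, nrow = 1L) else
    as.matrix(distances)
  if (length(catches) != ncol(d))
    stop("need one catch total per trap (column of the distance matrix)")
  if (any(catches < 0)) stop("catches must be nonnegative")
  if (any(d <= 0))
    stop("catch index undefined at zero distance: all d_xi must be > 0")
  if (variant == "displayed") {
    as.vector(d^-2 %*% catches)
  } else {
    sqrt(as.vector((d^-2) %*% catches^2))
  }
}

#' Project lon/lat to local planar meters
#'
#' Local equirectangular projection about a reference point; adequate for
#' small extents (an orchard block, < ~2 km) where projection error is
#' negligible relative to GNSS error.
#'
#' @param lonlat two-column matrix of longitude, latitude in degrees.
#' @param center optional length-2 lon/lat origin; default the centroid.
#' @return Two-column matrix of x,y meters relative to `center`.
#' @export
lonlat_to_local <- function(lonlat, center = NULL) {
  ll <- as.matrix(lonlat)
  stopifnot(ncol(ll) == 2L)
  if (is.null(center)) center <- colMeans(ll)
  r_earth <- 6371008.8  # mean Earth radius, meters
  to_rad <- pi / 180
  x <- (ll[, 1L] - center[1L]) * to_rad * r_earth * cos(center[2L] * to_rad)
  y <- (ll[, 2L] - center[2L]) * to_rad * r_earth
  cbind(x = x, y = y)
}
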