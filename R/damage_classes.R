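#' Six-class fruit injury scheme
#'
#' Fruit are scored into ordered damage classes by the number of feeding
#' injuries per fruit; each class carries a damage coefficient `V` used to
#' compute damage severity. The default scheme is the standard six-class
#' scale for stink bug feeding damage on apple: class 1 = no injury
#' (V = 0), class 2 = 1 injury (V = 1), class 3 = 2-3 (V = 2.5),
#' class 4 = 4-6 (V = 5), class 5 = 7-10 (V = 8.5), class 6 = 11-20
#' (V = 15.5). Injury counts above the top range are clamped into the top
#' class.
#'
#' @param classes data.frame with columns `class`, `injury_min`,
#'   `injury_max`, `V`. Ranges must be disjoint, contiguous from 0 and
#'   strictly increasing; `V` must be nondecreasing and zero exactly for
#'   the no-injury class.
#' @return An object of class `damage_class_scheme` (a validated
#'   data.frame).
#' @examples
#' sch <- damage_class_scheme()
#' sch$V
#' @export
damage_class_scheme <- function(classes = NULL) {
  if (is.null(classes)) {
    classes <- data.frame(
      class      = 1:6,
      injury_min = c(0, 1, 2, 4, 7, 11),
      injury_max = c(0, 1, 3, 6, 10, 20),
      V          = c(0, 1, 2.5, 5, 8.5, 15.5)
    )
  }
  stopifnot(is.data.frame(classes),
            all(c("class", "injury_min", "injury_max", "V") %in% names(classes)))
  k <- nrow(classes)
  if (k < 2L) stop("a damage class scheme needs at least two classes")
  if (any(classes$injury_min > classes$injury_max))
    stop("each class needs injury_min <= injury_max")
  if (classes$injury_min[1L] != 0L)
    stop("injury ranges must start at 0")
  if (any(classes$injury_min[-1L] != classes$injury_max[-k] + 1L))
    stop("injury ranges must be disjoint and contiguous")
  if (any(diff(classes$V) < 0))
    stop("damage coefficients V must be nondecreasing across classes")
  zeroV <- classes$V == 0
  zeroRange <- classes$injury_min == 0 & classes$injury_max == 0
  if (!identical(zeroV, zeroRange))
    stop("V must be 0 exactly for the class whose injury range is {0}")
  structure(classes, class = c("damage_class_scheme", "data.frame"))
}

#' Assign an injury count to a damage class
#'
#' @param injuries integer vector of feeding-injury counts per fruit
#'   (nonnegative).
#' @param scheme a [damage_class_scheme()].
#' @return Integer vector of class labels; counts above the scheme's top
#'   range map to the top class.
#' @examples
#' assign_class(c(0, 3, 25))
#' @export
assign_class <- function(injuries, scheme = damage_class_scheme()) {
  if (any(is.na(injuries)) || any(injuries < 0))
    stop("injury counts must be nonnegative and non-missing")
  # upper bounds define the bins; clamp above the top range
  idx <- findInterval(pmin(injuries, max(scheme$injury_max)),
                      c(scheme$injury_min))
  scheme$class[idx]
}

.class_count_matrix <- function(class_counts, n_classes) {
  m <- if (is.matrix(class_counts)) class_counts else
    matrix(class_counts, nrow = 1L)
  if (ncol(m) != n_classes)
    stop("class_counts must have one entry per class of the scheme")
  if (any(is.na(m)) || any(m < 0))
    stop("class counts must be nonnegative and non-missing")
  m
}

#' Fruit damage incidence (% of injured fruit)
#'
#' Incidence is the percentage of assessed fruit carrying at least one
#' feeding injury: `100 * (total - n_class1) / total`, where class 1 is
#' the no-injury class.
#'
#' @param class_counts numeric vector of per-class fruit counts (class 1
#'   first), or a matrix with one row per assessment point.
#' @param scheme a [damage_class_scheme()]; only its number of classes is
#'   used here.
#' @return Numeric vector of incidences in `[0, 100]`.
#' @examples
#' damage_incidence(c(82, 10, 0, 0, 0, 0))
#' @export
damage_incidence <- function(class_counts, scheme = damage_class_scheme()) {
  m <- .class_count_matrix(class_counts, nrow(scheme))
  total <- rowSums(m)
  if (any(total <= 0))
    stop("damage incidence is undefined for points with zero assessed fruit")
  100 * (total - m[, 1L]) / total
}

#' Fruit damage severity (mean injuries per injured fruit)
#'
#' Severity is the weighted mean of the damage coefficients `V` over
#' injured fruit only: `sum_{i>=2} N_i V_i / sum_{i>=2} N_i`. Uninjured
#' (class 1) fruit never enter either sum, so a point's severity is the
#' average injury load of its damaged fruit. Points with no injured fruit
#' have undefined severity and return `NA` (never 0); downstream tables
#' carry the value as missing.
#'
#' @inheritParams damage_incidence
#' @return Numeric vector of severities (`NA` where no fruit is injured).
#' @examples
#' damage_severity(c(0, 4, 2, 1, 0, 0))  # (4*1 + 2*2.5 + 1*5) / 7 = 2
#' @export
damage_severity <- function(class_counts, scheme = damage_class_scheme()) {
  m <- .class_count_matrix(class_counts, nrow(scheme))
  inj <- m[, -1L, drop = FALSE]
  n_inj <- rowSums(inj)
  sev <- as.vector(inj %*% scheme$V[-1L]) / n_inj
  sev[n_inj == 0] <- NA_real_
  sev
}
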