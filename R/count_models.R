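#' Fit a log-link count regression
#'
#' Maximum-likelihood Poisson or negative binomial regression with log
#' link, the workhorse for trap-catch counts and for injured-fruit counts
#' with a log-exposure offset. Poisson fits use [stats::glm()]; negative
#' binomial fits jointly estimate the dispersion parameter theta via
#' [MASS::glm.nb()]. Offsets are declared inside the formula with
#' `offset(log(exposure))` so that prediction on new data works
#' unchanged.
#'
#' @param formula model formula; response must be a nonnegative integer
#'   count.
#' @param data data.frame holding response, covariates and any exposure
#'   column named in an `offset()` term.
#' @param family `"poisson"` or `"negative_binomial"`.
#' @return The fitted model (`glm`, or `negbin` from MASS), with the
#'   usual accessors: `coef()`, `vcov()`, `logLik()`, `AIC()`,
#'   `fitted()`; negative binomial fits expose the dispersion as
#'   `$theta`. An attribute `count_family` records the requested family.
#' @examples
#' d <- data.frame(y = c(2, 4, 6))
#' coef(fit_count_model(y ~ 1, d))  # log(4)
#' @export
fit_count_model <- function(formula, data,
                            family = c("poisson", "negative_binomial")) {
  family <- match.arg(family)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (any(y < 0)) stop("negative response: counts must be nonnegative")
  if (any(abs(y - round(y)) > 1e-8))
    stop("non-integer response: counts must be whole numbers")
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design matrix: drop aliased terms")
  if (nrow(X) < ncol(X))
    stop("more parameters than observations")
  fit <- if (family == "poisson") {
    stats::glm(formula, data = data, family = stats::poisson(link = "log"))
  } else {
    MASS::glm.nb(formula, data = data)
  }
  if (!isTRUE(fit$converged))
    stop("count model did not converge")
  # embed the data so update()/stepAIC() refits work from any frame
  fit$call$data <- data
  attr(fit, "count_family") <- family
  fit
}

.count_family <- function(fit) {
  fam <- attr(fit, "count_family")
  if (!is.null(fam)) return(fam)
  if (inherits(fit, "negbin")) "negative_binomial" else "poisson"
}

#' Likelihood-ratio analysis of deviance for nested count models
#'
#' Twice the log-likelihood gap between a full model and a model nested
#' within it, referred to the chi-square distribution with the difference
#' in parameter count as degrees of freedom.
#'
#' @param full,reduced fitted models from [fit_count_model()] on the same
#'   data, `reduced` nested in `full`.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
anova_deviance <- function(full, reduced) {
  canon <- function(obj) {
    tl <- attr(stats::terms(obj), "term.labels")
    vapply(strsplit(tl, ":", fixed = TRUE),
           function(v) paste(sort(v), collapse = ":"), character(1L))
  }
  tf <- canon(full)
  tr <- canon(reduced)
  if (!all(tr %in% tf))
    stop("models are not nested: every term of 'reduced' must appear in 'full'")
  if (stats::nobs(full) != stats::nobs(reduced))
    stop("models were fitted to different numbers of observations")
  llf <- stats::logLik(full)
  llr <- stats::logLik(reduced)
  df <- attr(llf, "df") - attr(llr, "df")
  if (df < 0) stop("'reduced' has more parameters than 'full'")
  stat <- max(0, 2 * (as.numeric(llf) - as.numeric(llr)))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p.value = p)
}

.drop_term <- function(formula, term, also_containing = FALSE) {
  tl <- attr(stats::terms(formula), "term.labels")
  facs <- attr(stats::terms(formula), "factors")
  drop <- term
  if (also_containing && term %in% colnames(facs)) {
    vars <- rownames(facs)[facs[, term] > 0]
    contains <- vapply(tl, function(t)
      all(vars %in% rownames(facs)[facs[, t] > 0]), logical(1L))
    drop <- tl[contains]
  }
  keep <- setdiff(tl, drop)
  rhs <- if (length(keep)) paste(keep, collapse = " + ") else "1"
  off <- attr(stats::terms(formula), "offset")
  if (!is.null(off)) {
    ov <- vapply(off, function(i) deparse(attr(stats::terms(formula),
                                               "variables")[[i + 1L]]),
                 character(1L))
    rhs <- paste(c(rhs, ov), collapse = " + ")
  }
  stats::reformulate(rhs, response = formula[[2L]])
}

#' Term-wise analysis-of-deviance table (type II / III)
#'
#' Likelihood-ratio chi-square test for each term of a fitted count
#' model. Type III removes each term's columns from the full design
#' matrix (treatment coding), so a main effect is tested with its
#' interactions still present; type II tests each term against the model
#' containing all terms that do not involve it, respecting marginality
#' (a main effect is tested without its interactions present).
#'
#' @param fit a model from [fit_count_model()].
#' @param data the data used to fit it.
#' @param type `"III"` or `"II"`.
#' @return data.frame with one row per term: `term`, `statistic`, `df`,
#'   `p.value`.
#' @export
deviance_table <- function(fit, data, type = c("III", "II")) {
  type <- match.arg(type)
  family <- .count_family(fit)
  form <- stats::formula(fit)
  tl <- attr(stats::terms(form), "term.labels")
  facs <- attr(stats::terms(form), "factors")
  if (type == "III") {
    X <- stats::model.matrix(fit)
    asgn <- attr(X, "assign")
    y <- fit$y
    if (is.null(y)) y <- stats::model.response(stats::model.frame(fit))
    off <- fit$offset
    if (is.null(off)) off <- rep(0, length(y))
    llf <- as.numeric(stats::logLik(fit))
    rows <- lapply(seq_along(tl), function(i) {
      keep <- asgn != i
      red <- .refit_matrix(X[, keep, drop = FALSE], y, off, family)
      stat <- max(0, 2 * (llf - as.numeric(stats::logLik(red))))
      df <- sum(!keep)
      data.frame(term = tl[i], statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE))
    })
  } else {
    rows <- lapply(tl, function(term) {
      # baseline excludes the term and everything containing it
      vars <- rownames(facs)[facs[, term] > 0]
      containing <- tl[vapply(tl, function(t)
        all(vars %in% rownames(facs)[facs[, t] > 0]), logical(1L))]
      reduced_form <- .drop_term(form, term, also_containing = TRUE)
      keep <- setdiff(tl, setdiff(containing, term))
      rhs <- if (length(keep)) paste(keep, collapse = " + ") else "1"
      off <- attr(stats::terms(form), "offset")
      if (!is.null(off)) {
        ov <- vapply(off, function(i) deparse(attr(stats::terms(form),
                                                   "variables")[[i + 1L]]),
                     character(1L))
        rhs <- paste(c(rhs, ov), collapse = " + ")
      }
      full_form <- stats::reformulate(rhs, response = form[[2L]])
      full_fit <- suppressWarnings(fit_count_model(full_form, data, family))
      reduced_fit <- suppressWarnings(fit_count_model(reduced_form, data,
                                                      family))
      a <- anova_deviance(full_fit, reduced_fit)
      data.frame(term = term, statistic = a$statistic, df = a$df,
                 p.value = a$p.value)
    })
  }
  do.call(rbind, rows)
}

# refit on an explicit design matrix (used by type III column drops)
.refit_matrix <- function(Xr, y, off, family) {
  dd <- data.frame(y_ = y, off_ = off)
  dd$Xr_ <- Xr
  if (family == "poisson")
    stats::glm(y_ ~ Xr_ - 1 + offset(off_), data = dd,
               family = stats::poisson())
  else
    suppressWarnings(MASS::glm.nb(y_ ~ Xr_ - 1 + offset(off_), data = dd))
}

#' Backward AIC term selection
#'
#' Starting from a full count model, iteratively removes the term whose
#' deletion most lowers the AIC (respecting marginality: main effects are
#' never dropped while an interaction containing them remains) until no
#' deletion lowers it, and returns the minimum-AIC model together with
#' the drop log. Selection is delegated to [MASS::stepAIC()], the
#' standard backward-elimination machinery for these models.
#'
#' @inheritParams fit_count_model
#' @return list with `fit` (the retained model), `log` (the stepwise
#'   anova table), and `dropped` (character vector of removed terms).
#' @export
backward_aic <- function(formula, data,
                         family = c("poisson", "negative_binomial")) {
  family <- match.arg(family)
  full <- fit_count_model(formula, data, family)
  best <- suppressWarnings(
    MASS::stepAIC(full, direction = "backward", trace = FALSE))
  attr(best, "count_family") <- family
  kept <- attr(stats::terms(best), "term.labels")
  dropped <- setdiff(attr(stats::terms(full), "term.labels"), kept)
  list(fit = best, log = best$anova, dropped = dropped)
}

#' Pearson chi-square goodness of fit
#'
#' `sum((y - mu)^2 / V(mu))` with the family variance (`mu` for Poisson,
#' `mu + mu^2/theta` for the negative binomial) on `n - p` residual
#' degrees of freedom, plus the dispersion ratio `chi^2 / df`. A
#' dispersion ratio well above 1 flags overdispersion relative to the
#' fitted family.
#'
#' @param fit a model from [fit_count_model()].
#' @return list with `statistic`, `df`, `p.value`, `dispersion`.
#' @export
pearson_gof <- function(fit) {
  y <- fit$y
  if (is.null(y)) y <- stats::model.response(stats::model.frame(fit))
  mu <- stats::fitted(fit)
  v <- if (.count_family(fit) == "negative_binomial")
    mu + mu^2 / fit$theta else mu
  stat <- sum((y - mu)^2 / v)
  df <- fit$df.residual
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE),
       dispersion = stat / df)
}

#' One-way ANOVA on group totals
#'
#' Classical between/within F test, e.g. for per-trap season totals
#' across trap sets or sites.
#'
#' @param groups named list of numeric vectors, one per group.
#' @return list with `statistic`, `df1`, `df2`, `p.value`.
#' @examples
#' oneway_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))  # F = 13.5
#' @export
oneway_anova <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) < 1L))
    stop("need at least two nonempty groups")
  d <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups) %||% seq_along(groups), lengths(groups))))
  if (nrow(d) <= nlevels(d$g))
    stop("need more observations than groups")
  # degenerate (zero-variance) cases are diagnosed below, not by aov
  tab <- suppressWarnings(stats::anova(stats::aov(y ~ g, data = d)))
  if (tab["Residuals", "Sum Sq"] <= 0 && tab["g", "Sum Sq"] <= 0)
    stop("zero within- and between-group variance: F undefined")
  if (tab["Residuals", "Sum Sq"] <= 0)
    stop("zero within-group variance: F undefined")
  list(statistic = tab["g", "F value"], df1 = tab["g", "Df"],
       df2 = tab["Residuals", "Df"], p.value = tab["g", "Pr(>F)"])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wald z test for a linear contrast of coefficients
#'
#' `z = c'beta / sqrt(c' Sigma c)` with a two-sided normal p-value; used
#' e.g. for the male-vs-female catch comparison within one trap part.
#'
#' @param fit a model from [fit_count_model()].
#' @param contrast numeric vector, one entry per model coefficient.
#' @return list with `estimate`, `se`, `z`, `p.value`.
#' @export
wald_contrast <- function(fit, contrast) {
  b <- stats::coef(fit)
  if (length(contrast) != length(b))
    stop("contrast length must equal the number of coefficients")
  if (all(contrast == 0))
    return(list(estimate = 0, se = 0, z = 0, p.value = 1))
  v <- as.numeric(t(contrast) %*% stats::vcov(fit) %*% contrast)
  if (!is.finite(v) || v <= 0)
    stop("singular coefficient covariance for this contrast")
  est <- sum(contrast * b)
  z <- est / sqrt(v)
  list(estimate = est, se = sqrt(v), z = z,
       p.value = 2 * stats::pnorm(-abs(z)))
}

#' Serializable summary of a fitted count model
#'
#' Flattens a fitted model into plain vectors/matrices for JSON reports.
#'
#' @param fit a model from [fit_count_model()].
#' @return list with coefficients, covariance, theta (NA for Poisson),
#'   log-likelihood, AIC, n, p and the Pearson goodness of fit.
#' @export
count_fit_summary <- function(fit) {
  gof <- pearson_gof(fit)
  list(
    family = .count_family(fit),
    formula = paste(deparse(stats::formula(fit)), collapse = " "),
    coefficients = as.list(stats::coef(fit)),
    vcov = unname(as.matrix(stats::vcov(fit))),
    theta = if (.count_family(fit) == "negative_binomial")
      unname(fit$theta) else NA,
    logLik = as.numeric(stats::logLik(fit)),
    AIC = stats::AIC(fit),
    n = stats::nobs(fit),
    p = length(stats::coef(fit)),
    pearson_chisq = gof$statistic,
    pearson_df = gof$df,
    pearson_p = gof$p.value,
    dispersion_ratio = gof$dispersion
  )
}
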