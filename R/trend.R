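# Cross-field-strength statistics: the square-root field-ratio scaling
# law, through-origin trend fits, TOST equivalence and Bland-Altman
# agreement summaries.

#' Theoretical artifact-area scaling factor between field strengths
#'
#' The artifact area at a target field is predicted as
#' `sqrt(B_final / B_initial)` times the area at the initial field.
#'
#' @param B_initial,B_final Field strengths in tesla, > 0.
#' @return The unitless factor `sqrt(B_final / B_initial)`.
#' @examples
#' theoretical_slope(1.5, 3)   # 1.41
#' theoretical_slope(1.5, 7)   # 2.16
#' @export
theoretical_slope <- function(B_initial, B_final) {
  if (any(B_initial <= 0) || any(B_final <= 0)) {
    stop("domain error: field strengths must be > 0")
  }
  sqrt(B_final / B_initial)
}

#' Predict an artifact area at another field strength
#'
#' @param area_initial Artifact area (any consistent unit), >= 0.
#' @param B_initial,B_final Field strengths in tesla.
#' @return Predicted area in the same unit.
#' @export
predict_artifact_size <- function(area_initial, B_initial, B_final) {
  if (any(area_initial < 0)) stop("domain error: areas must be >= 0")
  area_initial * theoretical_slope(B_initial, B_final)
}

#' Through-origin trend fit of paired artifact areas
#'
#' Least-squares slope of high-field areas against low-field areas for the
#' same test configurations.  The default model is a pure proportionality
#' through the origin (the scaling law has no offset); the slope's 95%
#' confidence interval uses the normal-theory standard error with n - 1
#' degrees of freedom, and R^2 uses the uncentered (through-origin)
#' convention `1 - SS_res / sum(y^2)`.  An intercept variant is available
#' for sensitivity checks.
#'
#' @param area_low Areas at the lower field (vector), or a data frame /
#'   list with elements `area_low` and `area_high`.
#' @param area_high Areas at the higher field (same length, same unit).
#' @param include_intercept Fit `y ~ x` instead of `y ~ 0 + x`.
#' @param conf_level Confidence level for the slope interval.
#' @return Object of class `trend_fit`: `slope`, `se`, `ci95`,
#'   `r_squared`, `n`, `df`, `intercept` (NA for the default model).
#' @examples
#' fit_trend(c(1, 2, 3), c(2, 4, 6))  # slope 2, R^2 = 1
#' @export
fit_trend <- function(area_low, area_high = NULL, include_intercept = FALSE,
                      conf_level = 0.95) {
  if (is.null(area_high)) {
    area_high <- area_low$area_high
    area_low <- area_low$area_low
  }
  x <- as.numeric(area_low); y <- as.numeric(area_high)
  if (length(x) != length(y)) stop("dimension error: unequal lengths")
  n <- length(x)
  if (n < 2L) stop("degenerate fit: need at least 2 pairs")
  if (all(x == 0)) stop("degenerate fit: all low-field areas are zero")
  if (include_intercept) {
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
    se <- summary(fit)$coefficients[2L, 2L]
    dof <- n - 2L
    r2 <- summary(fit)$r.squared
  } else {
    sxx <- sum(x^2)
    slope <- sum(x * y) / sxx
    res <- y - slope * x
    dof <- n - 1L
    se <- sqrt(sum(res^2) / dof / sxx)
    r2 <- 1 - sum(res^2) / sum(y^2)
    intercept <- NA_real_
  }
  tq <- stats::qt(1 - (1 - conf_level) / 2, dof)
  structure(list(slope = slope, se = se,
                 ci95 = c(slope - tq * se, slope + tq * se),
                 r_squared = r2, n = n, df = dof, intercept = intercept,
                 conf_level = conf_level),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> slope %.4f (%g%% CI %.4f - %.4f), R^2 %.4f, n = %d%s\n",
              x$slope, 100 * x$conf_level, x$ci95[1], x$ci95[2],
              x$r_squared, x$n,
              if (is.na(x$intercept)) " (through origin)"
              else sprintf(", intercept %.3f", x$intercept)))
  invisible(x)
}

#' @export
coef.trend_fit <- function(object, ...) {
  if (is.na(object$intercept)) c(slope = object$slope)
  else c(intercept = object$intercept, slope = object$slope)
}

#' @export
confint.trend_fit <- function(object, parm = "slope", level = NULL, ...) {
  if (!is.null(level) && level != object$conf_level) {
    tq <- stats::qt(1 - (1 - level) / 2, object$df)
    return(c(object$slope - tq * object$se, object$slope + tq * object$se))
  }
  object$ci95
}

#' @export
predict.trend_fit <- function(object, newdata, ...) {
  x <- if (is.list(newdata)) newdata$area_low else newdata
  b0 <- if (is.na(object$intercept)) 0 else object$intercept
  b0 + object$slope * x
}

#' @export
plot.trend_fit <- function(x, area_low, area_high, ...) {
  graphics::plot(area_low, area_high,
                 xlab = "artifact area, lower field",
                 ylab = "artifact area, higher field", ...)
  graphics::abline(a = if (is.na(x$intercept)) 0 else x$intercept,
                   b = x$slope, lty = 2)
  invisible(x)
}

#' Two one-sided tests (TOST) for equivalence of paired artifact sizes
#'
#' One-sample TOST on per-configuration differences: one-sided t-tests
#' that the mean difference exceeds `-bound` and falls below `+bound`.
#' Equivalence is declared iff both p-values are below `alpha`.  With zero
#' variance the test degenerates to an exact comparison of the mean with
#' the bounds (p = 0 inside, p = 1 outside).
#'
#' @param differences Paired differences (pixels).
#' @param bound Equivalence bound (same unit), > 0; default 200 px, the
#'   averaged one-pixel uncertainty of the validation study.
#' @param alpha Significance level.
#' @return Object of class `equivalence_test`: `mean_diff`, `sd`, `n`,
#'   `bound`, `p_lower`, `p_upper`, `alpha`, `equivalent`.
#' @export
equivalence_test <- function(differences, bound = 200, alpha = 0.05) {
  d <- as.numeric(differences)
  n <- length(d)
  if (n < 2L) stop("insufficient data: need at least 2 differences")
  if (!is.numeric(bound) || bound <= 0) stop("'bound' must be > 0")
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    p_lower <- if (m > -bound) 0 else 1
    p_upper <- if (m < bound) 0 else 1
  } else {
    sem <- s / sqrt(n)
    p_lower <- stats::pt((m + bound) / sem, n - 1L, lower.tail = FALSE)
    p_upper <- stats::pt((m - bound) / sem, n - 1L, lower.tail = TRUE)
  }
  structure(list(mean_diff = m, sd = s, n = n, bound = bound,
                 p_lower = p_lower, p_upper = p_upper, alpha = alpha,
                 equivalent = (p_lower < alpha) && (p_upper < alpha)),
            class = "equivalence_test")
}

#' @export
print.equivalence_test <- function(x, ...) {
  cat(sprintf(paste0("<equivalence_test> mean diff %.2f (n = %d), bound +/- %g: ",
                     "p_lower %.3g, p_upper %.3g -> %sequivalent at alpha %g\n"),
              x$mean_diff, x$n, x$bound, x$p_lower, x$p_upper,
              if (x$equivalent) "" else "NOT ", x$alpha))
  invisible(x)
}

#' Bland-Altman agreement summary
#'
#' Per-pair means and differences, the bias (mean difference) and the
#' limits of agreement `bias +/- 1.96 SD`.
#'
#' @param areas_a,areas_b Paired collections (equal length >= 2).
#' @return Object of class `bland_altman`: data frame `points` (mean,
#'   diff), `bias`, `sd`, `limits` (ordered lower, upper).
#' @export
bland_altman <- function(areas_a, areas_b) {
  a <- as.numeric(areas_a); b <- as.numeric(areas_b)
  if (length(a) != length(b)) stop("dimension error: unequal lengths")
  if (length(a) < 2L) stop("insufficient data: need at least 2 pairs")
  d <- b - a
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(points = data.frame(mean = (a + b) / 2, diff = d),
                 bias = bias, sd = s,
                 limits = c(bias - 1.96 * s, bias + 1.96 * s)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.3f, limits of agreement [%.3f, %.3f], n = %d\n",
              x$bias, x$limits[1], x$limits[2], nrow(x$points)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$points$mean, x$points$diff,
                 xlab = "pair mean", ylab = "pair difference", ...)
  graphics::abline(h = c(x$bias, x$limits), lty = c(1, 2, 2))
  invisible(x)
}
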