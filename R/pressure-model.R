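# Depth power law of pressure inhibition: in-situ activity as a percentage
# of depressurized activity, P = a * z^b, fitted by OLS in log10-log10
# space; plus the type-III ANCOVA comparing slopes of two depth profiles.

#' Fit the depth power law
#'
#' Ordinary least squares of `log10(P)` on `log10(z)`, where `P` is the
#' in-situ activity as percent of the mean atmospheric-pressure activity and
#' `z` is depth in metres. The fit is unweighted, matching the usual log-log
#' treatment of such profiles. Zero-depth instrument-test points (which are
#' not depth observations) are excluded by default.
#'
#' @param points data.frame with columns `depth_m` and `p_percent` (a
#'   `below_detection` column, when present, drops flagged rows).
#' @param exclude_zero_depth drop points with `depth_m <= 0` (default TRUE).
#' @return An object of class `power_law_fit`: `a` (percent at z = 1 m),
#'   `b` (exponent), `r2`, `n`, `se` and 95% confidence intervals for
#'   `log10_a` and `b` (t distribution, n - 2 df), and `sigma` (residual
#'   s.d., log10 units).
#' @export
#' @examples
#' z <- c(200, 500, 1000, 2000, 4000)
#' fit <- fit_power_law(data.frame(depth_m = z, p_percent = 494 * z^-0.321))
#' c(fit$a, fit$b)
fit_power_law <- function(points, exclude_zero_depth = TRUE) {
  stopifnot(is.data.frame(points),
            all(c("depth_m", "p_percent") %in% names(points)))
  if (!is.null(points$below_detection))
    points <- points[!points$below_detection, ]
  if (exclude_zero_depth) points <- points[points$depth_m > 0, ]
  if (any(points$depth_m <= 0))
    stop("non-positive depths in the regression set", call. = FALSE)
  if (any(points$p_percent <= 0))
    stop("non-positive ratio values in the regression set", call. = FALSE)
  n <- nrow(points)
  if (n < 3L) stop("need at least 3 points with z > 0", call. = FALSE)
  m <- stats::lm(log10(p_percent) ~ log10(depth_m), data = points)
  # zero-residual fits are legitimate here (noiseless validation data)
  sm <- suppressWarnings(summary(m))
  co <- sm$coefficients
  tcrit <- stats::qt(0.975, df = n - 2)
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  structure(list(
    a = 10^est[[1]], b = est[[2]],
    log10_a = est[[1]],
    se = c(log10_a = se[[1]], b = se[[2]]),
    ci = list(log10_a = est[[1]] + c(-1, 1) * tcrit * se[[1]],
              b = est[[2]] + c(-1, 1) * tcrit * se[[2]]),
    r2 = sm$r.squared,
    sigma = sm$sigma,
    n = n), class = "power_law_fit")
}

#' Construct a power-law fit from known coefficients
#'
#' Wraps published or externally obtained coefficients so they can be used
#' with [predict_fraction()] and [correct_php()].
#'
#' @param a percent at z = 1 m (> 0).
#' @param b dimensionless exponent.
#' @return A `power_law_fit` with only `a` and `b` populated.
#' @export
power_law <- function(a, b) {
  stopifnot(is.finite(a), a > 0, is.finite(b))
  structure(list(a = a, b = b, n = NA_integer_), class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> P = %.4g * z^%.4g", x$a, x$b))
  if (!is.na(x$n)) cat(sprintf("  (n = %d, r2 = %.3f)", x$n, x$r2))
  cat("\n")
  if (!is.null(x$ci))
    cat(sprintf("  95%% CI: b in [%.4g, %.4g], a in [%.4g, %.4g]\n",
                x$ci$b[1], x$ci$b[2], 10^x$ci$log10_a[1], 10^x$ci$log10_a[2]))
  invisible(x)
}

#' Predicted in-situ activity as percent of atmospheric activity
#'
#' Evaluates `a * z^b`. Since the uncapped curve exceeds 100% above roughly
#' 145 m with the canonical coefficients, predictions are capped at 100% by
#' default: the correction expresses inhibition and is meant for meso- and
#' bathypelagic depths.
#'
#' @param z depth(s), metres (> 0).
#' @param fit a `power_law_fit` (from [fit_power_law()] or [power_law()]).
#' @param cap_at_100 cap the prediction at 100 percent (default TRUE).
#' @return percent, same length as `z`.
#' @export
#' @examples
#' predict_fraction(4000, power_law(494, -0.321))
predict_fraction <- function(z, fit, cap_at_100 = TRUE) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (any(z <= 0)) stop("z must be > 0", call. = FALSE)
  p <- fit$a * z^fit$b
  if (cap_at_100) p <- pmin(p, 100)
  p
}

#' Correct an atmospheric-pressure production rate to in-situ pressure
#'
#' `PHP_insitu = PHP_atm * predict_fraction(z) / 100`.
#'
#' @param php_atm production under atmospheric pressure (>= 0), any
#'   volumetric rate unit.
#' @param z depth, metres (> 0).
#' @param fit a `power_law_fit`.
#' @param cap_at_100 passed to [predict_fraction()].
#' @return corrected rate, same unit as `php_atm`.
#' @export
correct_php <- function(php_atm, z, fit, cap_at_100 = TRUE) {
  if (any(php_atm < 0)) stop("php_atm must be >= 0", call. = FALSE)
  php_atm * predict_fraction(z, fit, cap_at_100) / 100
}

#' Compare the slopes of two log-log depth profiles (type-III ANCOVA)
#'
#' Fits a linear model of `log10(rate)` on condition, `log10(depth)` and
#' their interaction on the pooled data, and returns the type-III F test of
#' the interaction term, i.e. the test that the two power-law exponents
#' differ.
#'
#' @param profile_a,profile_b data.frames with `depth_m` and `rate` columns
#'   (positive), >= 3 points each.
#' @param labels group labels, length 2.
#' @return A list of class `slope_comparison`: `f`, `p`, `df` (numerator,
#'   denominator), `labels`.
#' @export
compare_slopes <- function(profile_a, profile_b, labels = c("A", "B")) {
  check <- function(d, lab) {
    stopifnot(is.data.frame(d), all(c("depth_m", "rate") %in% names(d)))
    if (nrow(d) < 3L) stop("need >= 3 points per profile", call. = FALSE)
    if (any(d$depth_m <= 0) || any(d$rate <= 0))
      stop("depths and rates must be positive", call. = FALSE)
    data.frame(logz = log10(d$depth_m), logr = log10(d$rate), grp = lab)
  }
  d <- rbind(check(profile_a, labels[1]), check(profile_b, labels[2]))
  d$grp <- factor(d$grp)
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op), add = TRUE)
  m <- stats::lm(logr ~ grp * logz, data = d)
  a3 <- car::Anova(m, type = 3)
  row <- grep(":", rownames(a3))
  f <- a3[row, "F value"]; p <- a3[row, "Pr(>F)"]
  if (!is.finite(f)) { f <- 0; p <- 1 }  # degenerate zero-residual case
  structure(list(f = f, p = p,
                 df = c(a3[row, "Df"], a3[nrow(a3), "Df"]),
                 labels = labels),
            class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("<slope_comparison> %s vs %s: F(%d, %d) = %.3g, p = %.3g\n",
              x$labels[1], x$labels[2], x$df[1], x$df[2], x$f, x$p))
  invisible(x)
}
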