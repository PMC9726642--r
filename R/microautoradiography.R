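# Microautoradiography quantification: silver-grain halo areas -> halo
# volumes -> single-cell leucine uptake rates via the bulk conversion
# regression; log-scale activity histograms; taxon-level paired tests.
#
# The weak beta radiation of tritium deposits silver grains in a
# (hemi)spherical cloud around an active cell, so halo *volume*, not area,
# is proportional to the amount of tracer taken up.

#' Halo volume from halo area
#'
#' Treats the measured halo area as the projected disc of a hemisphere
#' (default) or sphere of silver grains: `r = sqrt(A / pi)`, volume
#' `(2/3) pi r^3` or `(4/3) pi r^3`.
#'
#' @param area halo area(s), um^2 (>= 0).
#' @param geometry `"hemisphere"` (default) or `"sphere"`. Downstream
#'   uptake rates are invariant to this choice as long as the conversion
#'   regression uses the same geometry (the geometric constant cancels).
#' @return volume(s), um^3.
#' @export
#' @examples
#' halo_volume(pi)             # unit radius hemisphere: 2*pi/3
#' halo_volume(pi, "sphere")   # 4*pi/3
halo_volume <- function(area, geometry = c("hemisphere", "sphere")) {
  geometry <- match.arg(geometry)
  if (any(area < 0)) stop("halo area must be >= 0", call. = FALSE)
  r <- sqrt(area / pi)
  k <- if (geometry == "hemisphere") 2 / 3 else 4 / 3
  k * pi * r^3
}

#' Halo area from halo volume (inverse chain)
#'
#' @param volume halo volume(s), um^3 (>= 0).
#' @inheritParams halo_volume
#' @return area(s), um^2.
#' @export
area_from_volume <- function(volume, geometry = c("hemisphere", "sphere")) {
  geometry <- match.arg(geometry)
  if (any(volume < 0)) stop("halo volume must be >= 0", call. = FALSE)
  k <- if (geometry == "hemisphere") 2 / 3 else 4 / 3
  r <- (volume / (k * pi))^(1 / 3)
  pi * r^2
}

#' Fit the halo-volume conversion regression
#'
#' Through-origin least squares of the total halo volume production rate
#' `R_halo` (um^3 l^-1 h^-1) on the bulk leucine incorporation rate `R_leu`
#' (pmol Leu l^-1 h^-1): slope = sum(x y) / sum(x^2). The intercept is
#' forced to zero because no uptake produces no halo. `r2` is computed
#' about the through-origin model (1 - SS_res / sum(y^2)).
#'
#' @param bulk_rate numeric, pmol Leu l^-1 h^-1 (not all zero).
#' @param halo_volume_rate numeric, um^3 l^-1 h^-1, same length.
#' @return A list of class `conversion_fit`: `slope`, `r2`, `n`.
#' @export
#' @examples
#' fit_conversion(1, 9.72e7)$slope
fit_conversion <- function(bulk_rate, halo_volume_rate) {
  stopifnot(length(bulk_rate) == length(halo_volume_rate),
            length(bulk_rate) >= 1L)
  if (all(bulk_rate == 0)) stop("all bulk rates are zero", call. = FALSE)
  slope <- sum(bulk_rate * halo_volume_rate) / sum(bulk_rate^2)
  if (slope <= 0) stop("conversion slope must be positive", call. = FALSE)
  res <- halo_volume_rate - slope * bulk_rate
  r2 <- 1 - sum(res^2) / sum(halo_volume_rate^2)
  structure(list(slope = slope, r2 = r2, n = length(bulk_rate)),
            class = "conversion_fit")
}

#' @export
print.conversion_fit <- function(x, ...) {
  cat(sprintf("<conversion_fit> R_halo = %.4g * R_leu (n = %d, r2 = %.3f)\n",
              x$slope, x$n, x$r2))
  invisible(x)
}

#' Single-cell leucine uptake from halo volume
#'
#' Divides the per-cell halo production rate (volume over incubation time)
#' by the bulk conversion slope and rescales pmol -> amol (1e6) and
#' per-hour -> per-day (24):
#'
#' `u = volume / duration / slope * 1e6 * 24`  (amol Leu cell^-1 d^-1)
#'
#' @param volume halo volume(s), um^3.
#' @param duration_h incubation duration, hours (> 0).
#' @param fit a [fit_conversion()] result, or a bare positive slope.
#' @return uptake(s), amol Leu cell^-1 d^-1.
#' @export
#' @examples
#' cell_uptake(40.5, 10, 9.72e7)  # 1 amol cell^-1 d^-1
cell_uptake <- function(volume, duration_h, fit) {
  slope <- if (inherits(fit, "conversion_fit")) fit$slope else as.numeric(fit)
  if (!is.finite(duration_h) || duration_h <= 0)
    stop("duration_h must be > 0", call. = FALSE)
  if (slope <= 0) stop("conversion slope must be > 0", call. = FALSE)
  volume / duration_h / slope * 1e6 * 24
}

#' Halo volume implied by an uptake rate (inverse chain)
#'
#' @param uptake amol Leu cell^-1 d^-1.
#' @inheritParams cell_uptake
#' @return volume, um^3.
#' @export
uptake_to_volume <- function(uptake, duration_h, fit) {
  slope <- if (inherits(fit, "conversion_fit")) fit$slope else as.numeric(fit)
  stopifnot(duration_h > 0, slope > 0)
  uptake * duration_h * slope / (1e6 * 24)
}

#' Cell uptake table from a halo-area table
#'
#' Applies the full chain area -> volume -> uptake to a `cells.csv`-style
#' table. Cells with zero halo area are inactive and get zero uptake.
#'
#' @param cells data.frame with at least `halo_area_um2`; id/condition/
#'   taxon columns are carried through.
#' @param duration_h incubation duration, hours.
#' @param fit conversion fit or slope.
#' @inheritParams halo_volume
#' @return the input with `halo_volume_um3`, `uptake_amol_d` and `active`
#'   columns appended.
#' @export
cell_uptake_table <- function(cells, duration_h, fit,
                              geometry = c("hemisphere", "sphere")) {
  geometry <- match.arg(geometry)
  stopifnot(is.data.frame(cells), "halo_area_um2" %in% names(cells))
  cells$halo_volume_um3 <- halo_volume(cells$halo_area_um2, geometry)
  cells$uptake_amol_d <- cell_uptake(cells$halo_volume_um3, duration_h, fit)
  cells$active <- cells$halo_area_um2 > 0
  cells
}

#' Log10 activity histogram on a fixed binning
#'
#' Bins `log10(uptake)` of active cells into half-open intervals
#' `[e, e + h)` of uniform width `h`, anchored at a multiple of `h`. For
#' paired comparisons both histograms must share edges: anchor at the
#' floored grid position of the joint minimum (see
#' [build_paired_histograms()]).
#'
#' @param uptakes positive uptake rates of active cells, amol cell^-1 d^-1.
#' @param width bin width in log10 units (default 0.17).
#' @param anchor left edge origin (log10 units); default
#'   `floor(min(log10(u)) / width) * width`.
#' @param max_edge optional right limit (log10 units) the edges must reach.
#' @return Object of class `activity_histogram`: `edges`, `counts`,
#'   `n_active`, `width`, `anchor`.
#' @export
build_histogram <- function(uptakes, width = 0.17, anchor = NULL,
                            max_edge = NULL) {
  if (length(uptakes) == 0L) stop("no active cells", call. = FALSE)
  if (any(!is.finite(uptakes)) || any(uptakes <= 0))
    stop("uptakes must be positive (active cells only)", call. = FALSE)
  if (width <= 0) stop("bin width must be > 0", call. = FALSE)
  lx <- log10(uptakes)
  if (is.null(anchor)) anchor <- floor(min(lx) / width) * width
  if (min(lx) < anchor - 1e-12)
    stop("anchor lies above the smallest value", call. = FALSE)
  hi <- max(lx, if (!is.null(max_edge)) max_edge)
  nbin <- max(1L, ceiling((hi - anchor) / width + 1e-12))
  # half-open [e, e+h): a value exactly on an edge belongs to the bin above
  idx <- floor((lx - anchor) / width + 1e-12) + 1
  idx[idx > nbin] <- nbin
  counts <- tabulate(idx, nbins = nbin)
  structure(list(edges = anchor + width * (0:nbin), counts = counts,
                 n_active = length(uptakes), width = width, anchor = anchor),
            class = "activity_histogram")
}

#' @export
print.activity_histogram <- function(x, ...) {
  cat(sprintf(
    "<activity_histogram> %d active cells, %d bins of width %.3g from %.3g\n",
    x$n_active, length(x$counts), x$width, x$anchor))
  invisible(x)
}

#' Paired histograms on shared edges
#'
#' Builds the in-situ and atmospheric histograms on one common binning,
#' anchored at the floor-to-grid of the joint minimum, as required by the
#' bin-shift classification.
#'
#' @param uptakes_insitu,uptakes_atm positive uptake vectors.
#' @inheritParams build_histogram
#' @return list with elements `in_situ` and `atmospheric`.
#' @export
build_paired_histograms <- function(uptakes_insitu, uptakes_atm,
                                    width = 0.17) {
  joint_min <- min(log10(uptakes_insitu), log10(uptakes_atm))
  joint_max <- max(log10(uptakes_insitu), log10(uptakes_atm))
  anchor <- floor(joint_min / width) * width
  list(in_situ = build_histogram(uptakes_insitu, width, anchor, joint_max),
       atmospheric = build_histogram(uptakes_atm, width, anchor, joint_max))
}

#' Histogram bin width selection
#'
#' `fixed` returns the configured constant (default 0.17 log10 units, the
#' width used for communities of about 1,800-6,500 scored cells).
#' `shimazaki` minimizes the Shimazaki-Shinomoto cost
#' `C(h) = (2 * mean(k) - var(k)) / h^2` over candidate widths, where `k`
#' are the bin counts. `scott` is `3.49 * sd * n^(-1/3)` and
#' `freedman_diaconis` is `2 * IQR * n^(-1/3)`. All widths are in the same
#' (log10) units as `samples`.
#'
#' @param samples numeric sample the histogram will be built on (log10
#'   uptake values), n >= 2 for the data-driven methods.
#' @param method one of `"fixed"`, `"shimazaki"`, `"scott"`,
#'   `"freedman_diaconis"`.
#' @param fixed_width constant returned by `method = "fixed"`.
#' @param n_candidates candidate grid size for `shimazaki`.
#' @return bin width `h`.
#' @export
bin_width <- function(samples,
                      method = c("fixed", "shimazaki", "scott",
                                 "freedman_diaconis"),
                      fixed_width = 0.17, n_candidates = 100L) {
  method <- match.arg(method)
  if (method == "fixed") return(fixed_width)
  n <- length(samples)
  if (n < 2L) stop("need n >= 2 for data-driven bin widths", call. = FALSE)
  switch(method,
    scott = 3.49 * stats::sd(samples) * n^(-1 / 3),
    freedman_diaconis = 2 * stats::IQR(samples) * n^(-1 / 3),
    shimazaki = {
      rng <- range(samples)
      span <- diff(rng)
      if (span == 0) return(fixed_width)
      nbins <- seq(2L, max(4L, n_candidates), by = 1L)
      cost <- vapply(nbins, function(nb) {
        h <- span / nb
        edges <- rng[1] + h * (0:nb)
        k <- tabulate(pmin(findInterval(samples, edges,
                                        rightmost.closed = TRUE), nb),
                      nbins = nb)
        m <- mean(k)
        v <- mean((k - m)^2)  # biased variance, per the cost definition
        (2 * m - v) / h^2
      }, numeric(1))
      span / nbins[which.min(cost)]
    })
}

#' Highly active cells above an uptake threshold
#'
#' @param uptakes uptake rates of active cells (non-empty).
#' @param threshold strict threshold, amol Leu cell^-1 d^-1 (default 0.5).
#' @return list with `count` (cells with `u > threshold`) and `fraction`
#'   (of active cells).
#' @export
highly_active_fraction <- function(uptakes, threshold = 0.5) {
  if (length(uptakes) == 0L) stop("no uptake values", call. = FALSE)
  cnt <- sum(uptakes > threshold)
  list(count = cnt, fraction = cnt / length(uptakes))
}

#' Paired comparison of per-sample mean uptakes for one taxon
#'
#' Pairs are per-sample (station x depth) mean uptakes under in-situ and
#' atmospheric pressure. Normality of the pair differences is checked with
#' the Shapiro-Wilk test at alpha = 0.05: a paired t-test is used when
#' normality is not rejected, a Wilcoxon signed-rank test otherwise.
#' All-zero differences are degenerate and return a flagged result with no
#' p value.
#'
#' @param insitu,atm paired numeric vectors (>= 3 pairs), aligned by
#'   sample.
#' @param taxon label carried through.
#' @param alternative test sidedness, as in [stats::t.test()]; the
#'   one-sided alternatives refer to `atm` relative to `insitu` (e.g.
#'   `"greater"` tests for higher uptake upon depressurization).
#' @param alpha level of the Shapiro-Wilk normality decision.
#' @return A list of class `paired_test_result`: `taxon`, `test_used`,
#'   `statistic`, `p`, `alternative`, `n`, `degenerate`.
#' @export
taxon_paired_test <- function(insitu, atm, taxon = NA_character_,
                              alternative = c("two.sided", "greater", "less"),
                              alpha = 0.05) {
  alternative <- match.arg(alternative)
  stopifnot(length(insitu) == length(atm))
  ok <- is.finite(insitu) & is.finite(atm)
  insitu <- insitu[ok]; atm <- atm[ok]
  if (length(insitu) < 3L) stop("need >= 3 pairs", call. = FALSE)
  d <- atm - insitu
  if (all(d == 0))
    return(structure(list(taxon = taxon, test_used = NA_character_,
                          statistic = NA_real_, p = NA_real_,
                          alternative = alternative, n = length(d),
                          degenerate = TRUE),
                     class = "paired_test_result"))
  normal <- if (length(unique(d)) < 3L) FALSE else
    stats::shapiro.test(d)$p.value >= alpha
  if (normal) {
    tt <- stats::t.test(atm, insitu, paired = TRUE,
                        alternative = alternative)
    res <- list(test_used = "paired_t", statistic = unname(tt$statistic),
                p = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(atm, insitu, paired = TRUE,
                                              alternative = alternative))
    res <- list(test_used = "wilcoxon_signed_rank",
                statistic = unname(wt$statistic), p = wt$p.value)
  }
  structure(c(list(taxon = taxon), res,
              list(alternative = alternative, n = length(d),
                   degenerate = FALSE)),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<paired_test_result> %s: degenerate (all differences 0)\n",
                x$taxon))
  } else {
    cat(sprintf("<paired_test_result> %s: %s, statistic = %.3g, p = %.3g (%s, n = %d)\n",
                x$taxon, x$test_used, x$statistic, x$p, x$alternative, x$n))
  }
  invisible(x)
}

#' Taxon-level paired tests across samples
#'
#' Computes per-sample mean uptakes for each taxon and condition from a
#' cell-uptake table and runs [taxon_paired_test()] per taxon. Taxa with
#' fewer than 3 complete paired samples are skipped.
#'
#' @param uptake_table data.frame with `sample_id`, `condition`, `taxon`,
#'   `uptake_amol_d` (e.g. from [cell_uptake_table()]).
#' @param alternative sidedness, passed through.
#' @return data.frame with one row per tested taxon.
#' @export
taxon_tests <- function(uptake_table, alternative = "greater") {
  stopifnot(all(c("sample_id", "condition", "taxon", "uptake_amol_d") %in%
                  names(uptake_table)))
  agg <- stats::aggregate(uptake_amol_d ~ sample_id + condition + taxon,
                          data = uptake_table, FUN = mean)
  out <- lapply(unique(agg$taxon), function(tx) {
    d <- agg[agg$taxon == tx, ]
    w <- stats::reshape(d, idvar = "sample_id", timevar = "condition",
                        direction = "wide")
    ci <- w[["uptake_amol_d.in_situ"]]
    ca <- w[["uptake_amol_d.atmospheric"]]
    if (is.null(ci) || is.null(ca)) return(NULL)
    ok <- is.finite(ci) & is.finite(ca)
    if (sum(ok) < 3L) return(NULL)
    r <- taxon_paired_test(ci[ok], ca[ok], taxon = tx,
                           alternative = alternative)
    data.frame(taxon = tx, test_used = r$test_used %||% NA_character_,
               statistic = r$statistic, p = r$p, n = r$n,
               degenerate = r$degenerate)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
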