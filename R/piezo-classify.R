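# Bin-shift decomposition of the active community into piezotolerant,
# piezosensitive and piezophilic fractions.
#
# The two conditions observe *different* cells (independently sampled
# filters), so individual cells cannot be tracked across conditions.
# Cells falling in the same activity bin under both conditions are
# piezotolerant; the unmatched (residual) histogram mass must have moved
# between bins. Any way of transporting the in-situ residual onto the
# atmospheric residual splits the moved mass into upward moves (higher
# activity upon depressurization: piezosensitive) and downward moves
# (piezophilic). Extremizing over all transport plans gives sharp minimum
# and maximum abundances for both classes.

MASS_TOL <- 1e-9

#' Piezotolerant fraction by histogram intersection
#'
#' Normalizes both histograms to their own active-cell totals and matches
#' mass bin by bin: `tolerant = sum_b min(p_in(b), p_atm(b))`. The per-bin
#' unmatched masses are returned as residuals; at each bin at most one
#' residual is nonzero and both residuals total the moved mass `M`.
#'
#' @param hist_in,hist_atm [build_histogram()] objects on identical edges.
#' @return list with `tolerant` (fraction), `residual_in`, `residual_atm`
#'   (numeric per-bin vectors), `m` (moved mass).
#' @export
match_tolerant <- function(hist_in, hist_atm) {
  stopifnot(inherits(hist_in, "activity_histogram"),
            inherits(hist_atm, "activity_histogram"))
  if (length(hist_in$edges) != length(hist_atm$edges) ||
      max(abs(hist_in$edges - hist_atm$edges)) > MASS_TOL)
    stop("histograms must share identical bin edges", call. = FALSE)
  p_in <- hist_in$counts / hist_in$n_active
  p_atm <- hist_atm$counts / hist_atm$n_active
  tol <- sum(pmin(p_in, p_atm))
  list(tolerant = tol,
       residual_in = pmax(p_in - p_atm, 0),
       residual_atm = pmax(p_atm - p_in, 0),
       m = 1 - tol)
}

#' Bounds on upward- and downward-moved mass
#'
#' Over all transport plans moving the in-situ residual mass onto the
#' atmospheric residual mass, bounds the mass moved to strictly higher bins
#' (`up`) and strictly lower bins (`down`). For every bin boundary `k` the
#' residual mass above `k` on the atmospheric side that exceeds the in-situ
#' residual above `k` must have crossed `k` upward, so
#' `up_min = max_k (A_>k - I_>k)+`, and symmetrically
#' `down_min = max_k (I_>k - A_>k)+`; the remaining mass can always be
#' routed to avoid further forced moves, giving `up_max = M - down_min` and
#' `down_max = M - up_min`.
#'
#' @param residual_in,residual_atm per-bin residual masses on the same
#'   binning (equal totals within tolerance, at most one of the two nonzero
#'   in any bin, as produced by [match_tolerant()]).
#' @param tol mass-balance tolerance (fraction of total mass).
#' @return list `up_min`, `up_max`, `down_min`, `down_max`, `m`.
#' @export
transport_bounds <- function(residual_in, residual_atm, tol = MASS_TOL) {
  stopifnot(length(residual_in) == length(residual_atm),
            all(residual_in >= -tol), all(residual_atm >= -tol))
  if (any(pmin(residual_in, residual_atm) > tol))
    stop("residual supports must be disjoint per bin (run match_tolerant first)",
         call. = FALSE)
  m_in <- sum(residual_in); m_atm <- sum(residual_atm)
  if (abs(m_in - m_atm) > tol)
    stop("residual totals differ beyond tolerance", call. = FALSE)
  m <- m_in
  cum_i <- cumsum(residual_in)
  cum_a <- cumsum(residual_atm)
  # A_>k - I_>k = (m - cum_a[k]) - (m - cum_i[k]) = cum_i[k] - cum_a[k]
  up_min <- max(0, cum_i - cum_a)
  down_min <- max(0, cum_a - cum_i)
  list(up_min = up_min, up_max = m - down_min,
       down_min = down_min, down_max = m - up_min, m = m)
}

#' Decompose paired activity histograms into piezo classes
#'
#' Composition of [match_tolerant()] and [transport_bounds()]:
#' piezosensitive mass moves to higher activity bins upon depressurization
#' (up), piezophilic mass to lower bins (down). Midpoints of the bounds are
#' reported as point estimates.
#'
#' @param hist_in histogram of the in-situ condition.
#' @param hist_atm histogram of the depressurized (atmospheric) condition.
#' @return Object of class `piezo_classification`: `tolerant`,
#'   `sensitive_min`, `sensitive_max`, `sensitive_mid`, `philic_min`,
#'   `philic_max`, `philic_mid`, `m` (moved mass), `width`, `anchor`.
#' @export
#' @examples
#' com <- gen_paired_community(syn_config(seed = 42))
#' ut <- com$truth
#' u_in <- ut$uptake_insitu[ut$condition == "in_situ"]
#' u_at <- ut$uptake_atm[ut$condition == "atmospheric"]
#' h <- build_paired_histograms(u_in, u_at)
#' classify_piezo(h$in_situ, h$atmospheric)
classify_piezo <- function(hist_in, hist_atm) {
  mt <- match_tolerant(hist_in, hist_atm)
  tb <- transport_bounds(mt$residual_in, mt$residual_atm)
  out <- structure(list(
    tolerant = mt$tolerant,
    sensitive_min = tb$up_min, sensitive_max = tb$up_max,
    sensitive_mid = (tb$up_min + tb$up_max) / 2,
    philic_min = tb$down_min, philic_max = tb$down_max,
    philic_mid = (tb$down_min + tb$down_max) / 2,
    m = mt$m, width = hist_in$width, anchor = hist_in$anchor),
    class = "piezo_classification")
  check_piezo_sums(out)
  out
}

check_piezo_sums <- function(x, tol = MASS_TOL) {
  frs <- c(x$tolerant, x$sensitive_min, x$sensitive_max, x$philic_min,
           x$philic_max)
  stopifnot(all(frs >= -tol), all(frs <= 1 + tol))
  stopifnot(abs(x$m - (1 - x$tolerant)) <= tol,
            x$sensitive_min <= x$sensitive_max + tol,
            x$philic_min <= x$philic_max + tol,
            abs(x$sensitive_min + x$philic_max - x$m) <= tol,
            abs(x$sensitive_max + x$philic_min - x$m) <= tol)
  invisible(x)
}

#' @export
print.piezo_classification <- function(x, ...) {
  cat("<piezo_classification> (fractions of active cells)\n")
  cat(sprintf("  piezotolerant:  %.1f%%\n", 100 * x$tolerant))
  cat(sprintf("  piezosensitive: %.1f%% [%.1f, %.1f]\n",
              100 * x$sensitive_mid, 100 * x$sensitive_min,
              100 * x$sensitive_max))
  cat(sprintf("  piezophilic:    %.1f%% [%.1f, %.1f]\n",
              100 * x$philic_mid, 100 * x$philic_min, 100 * x$philic_max))
  invisible(x)
}

#' Classify a paired community from uptake vectors
#'
#' Convenience wrapper: builds the shared-edge histograms and classifies.
#'
#' @param uptakes_insitu,uptakes_atm positive uptake vectors (active cells).
#' @param width histogram bin width in log10 units.
#' @return [classify_piezo()] result.
#' @export
classify_piezo_uptakes <- function(uptakes_insitu, uptakes_atm,
                                   width = 0.17) {
  h <- build_paired_histograms(uptakes_insitu, uptakes_atm, width)
  classify_piezo(h$in_situ, h$atmospheric)
}
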