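# Radiotracer inversion: scintillation counts -> bulk leucine incorporation
# rates -> in-situ:atmospheric ratio points.

# 1 Ci = 2.22e12 disintegrations per minute
CI_TO_DPM <- 2.22e12

#' Bulk leucine incorporation rate from scintillation counts
#'
#' Converts live and killed-control disintegrations per minute into a bulk
#' leucine incorporation rate:
#'
#' `rate = (mean(dpm_live) - mean(dpm_killed)) / 2.22e12 / SA * 1e9 / volume / duration`
#'
#' in pmol Leu l^-1 h^-1, where SA is the tracer specific activity in
#' Ci mmol^-1. The killed-control mean is subtracted from the live mean
#' (standard radiotracer practice with duplicate controls). Non-positive net
#' rates are retained but flagged `below_detection`, never clamped, so that
#' downstream exclusion stays explicit.
#'
#' @param dpm_live numeric vector of live-replicate DPM (>= 1 value).
#' @param dpm_killed numeric vector of killed-control DPM (>= 1 value).
#' @param specific_activity tracer specific activity, Ci mmol^-1 (> 0).
#' @param volume_l filtered volume, litres (> 0).
#' @param duration_h incubation duration, hours (> 0).
#' @return A list of class `leucine_rate`: `value` (pmol Leu l^-1 h^-1) and
#'   `below_detection`.
#' @export
#' @examples
#' leucine_rate(dpm_live = c(980, 1005, 1015), dpm_killed = c(95, 105),
#'              specific_activity = 110, volume_l = 0.04, duration_h = 10)
leucine_rate <- function(dpm_live, dpm_killed, specific_activity,
                         volume_l, duration_h) {
  dpm_live <- dpm_live[!is.na(dpm_live)]
  dpm_killed <- dpm_killed[!is.na(dpm_killed)]
  if (length(dpm_live) < 1L || length(dpm_killed) < 1L)
    stop("need at least one live and one killed replicate", call. = FALSE)
  if (!is.finite(volume_l) || volume_l <= 0)
    stop("volume_l must be > 0", call. = FALSE)
  if (!is.finite(duration_h) || duration_h <= 0)
    stop("duration_h must be > 0", call. = FALSE)
  if (!is.finite(specific_activity) || specific_activity <= 0)
    stop("specific_activity must be > 0", call. = FALSE)
  net <- mean(dpm_live) - mean(dpm_killed)
  value <- net / CI_TO_DPM / specific_activity * 1e9 / volume_l / duration_h
  structure(list(value = value, below_detection = value <= 0),
            class = "leucine_rate")
}

#' @export
print.leucine_rate <- function(x, ...) {
  cat(sprintf("<leucine_rate> %.4g pmol Leu l^-1 h^-1%s\n", x$value,
              if (x$below_detection) " [below detection]" else ""))
  invisible(x)
}

#' In-situ rate as a percentage of the mean atmospheric rate
#'
#' @param rate_insitu a [leucine_rate()] (or its numeric value).
#' @param rates_atm list of [leucine_rate()] objects (or numeric vector) for
#'   the matching atmospheric-pressure incubations.
#' @param depth_m depth carried through to the ratio point.
#' @return A list of class `ratio_point`: `depth_m`, `p_percent`, `n_atm`,
#'   `below_detection` (inherited from the in-situ rate; flagged points are
#'   excluded from the regression set).
#' @export
ratio_percent <- function(rate_insitu, rates_atm, depth_m = NA_real_) {
  bd <- FALSE
  if (inherits(rate_insitu, "leucine_rate")) {
    bd <- rate_insitu$below_detection
    rate_insitu <- rate_insitu$value
  }
  if (is.list(rates_atm))
    rates_atm <- vapply(rates_atm, function(r)
      if (inherits(r, "leucine_rate")) r$value else as.numeric(r), numeric(1))
  m <- mean(rates_atm)
  if (!is.finite(m) || m <= 0)
    stop("mean atmospheric rate must be > 0", call. = FALSE)
  structure(list(depth_m = depth_m, p_percent = 100 * rate_insitu / m,
                 n_atm = length(rates_atm), below_detection = bd),
            class = "ratio_point")
}

#' Convert a table of incubations to a table of rates
#'
#' Applies [leucine_rate()] to every row of an incubation table in the
#' `incubations.csv` schema (columns `station`, `depth_m`, `condition`,
#' `dpm_live_*`, `dpm_killed_*`, `sa_ci_per_mmol`, `volume_l`,
#' `duration_h`).
#'
#' @param incubations data.frame in the schema above.
#' @return data.frame with `station`, `depth_m`, `condition`,
#'   `rate_pmol_l_h`, `below_detection`.
#' @export
rates_from_incubations <- function(incubations) {
  live_cols <- grep("^dpm_live_", names(incubations), value = TRUE)
  killed_cols <- grep("^dpm_killed_", names(incubations), value = TRUE)
  if (length(live_cols) == 0L || length(killed_cols) == 0L)
    stop("incubation table lacks dpm_live_*/dpm_killed_* columns",
         call. = FALSE)
  out <- lapply(seq_len(nrow(incubations)), function(i) {
    r <- leucine_rate(as.numeric(incubations[i, live_cols]),
                      as.numeric(incubations[i, killed_cols]),
                      incubations$sa_ci_per_mmol[i],
                      incubations$volume_l[i],
                      incubations$duration_h[i])
    data.frame(station = incubations$station[i],
               depth_m = incubations$depth_m[i],
               condition = incubations$condition[i],
               rate_pmol_l_h = r$value,
               below_detection = r$below_detection)
  })
  do.call(rbind, out)
}

#' Ratio points from a rate table
#'
#' Pairs each station x depth's in-situ rate with the mean of its
#' atmospheric-pressure replicates and returns one ratio point per in-situ
#' sample. Points whose in-situ rate is below detection, or whose
#' atmospheric mean is non-positive, are dropped with a message.
#'
#' @param rates data.frame from [rates_from_incubations()].
#' @return data.frame with `station`, `depth_m`, `p_percent`, `n_atm`.
#' @export
ratio_points_from_rates <- function(rates) {
  key <- interaction(rates$station, rates$depth_m, drop = TRUE)
  pieces <- lapply(split(rates, key), function(d) {
    ins <- d[d$condition == "in_situ", ]
    atm <- d[d$condition == "atmospheric", ]
    if (nrow(ins) == 0L || nrow(atm) == 0L) return(NULL)
    m <- mean(atm$rate_pmol_l_h)
    if (!is.finite(m) || m <= 0) return(NULL)
    ok <- !ins$below_detection
    if (!any(ok)) return(NULL)
    data.frame(station = ins$station[ok], depth_m = ins$depth_m[ok],
               p_percent = 100 * ins$rate_pmol_l_h[ok] / m,
               n_atm = nrow(atm))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
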