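# Synthetic measurement generator. Emulates the three data streams of a
# pressure-comparison study: (1) paired in-situ / atmospheric-pressure bulk
# radiotracer incubations whose activity ratio decays with depth as a noisy
# power law, (2) paired single-cell communities observed by
# microautoradiography as silver-grain halo areas, and (3) depth-resolved
# inputs for the carbon budget.

#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the generators with validation. Defaults encode
#' the measurement structure of a deep-sea pressure-comparison study:
#' activity under in-situ pressure decays relative to depressurized activity
#' as `a * z^b` percent, the active community is an 85/10/5 mixture of
#' piezotolerant, piezosensitive and piezophilic cells, and piezosensitive
#' cells increase their uptake more than 100-fold upon depressurization.
#'
#' @param seed integer seed used by all generators.
#' @param depths depths (m) of the station grid; all `> 0`.
#' @param n_stations_per_depth stations per depth (the default grid of 14
#'   depths x 4 stations gives the 56 in-situ samples of the bulk design).
#' @param attenuation_coeff `a`: in-situ activity as percent of atmospheric
#'   at `z = 1` m.
#' @param attenuation_exp `b`: dimensionless depth exponent (negative).
#' @param ratio_noise_sigma s.d. of the log10 in-situ:atmospheric ratio.
#' @param class_fractions named numeric `(tolerant, sensitive, philic)`,
#'   non-negative, summing to 1.
#' @param base_log10_uptake_mu,base_log10_uptake_sigma parameters of the
#'   in-situ single-cell log10 uptake distribution (amol Leu cell^-1 d^-1).
#' @param sensitive_fold_median,sensitive_fold_sigma median (`> 1`) and
#'   log10-s.d. of the lognormal fold-increase of piezosensitive cells upon
#'   depressurization.
#' @param philic_fold_median,philic_fold_sigma median (in `(0, 1)`) and
#'   log10-s.d. of the lognormal fold-change of piezophilic cells upon
#'   depressurization.
#' @param halo_noise_cv relative s.d. of the multiplicative measurement
#'   noise on halo areas.
#' @param conversion_slope slope of the halo-volume conversion regression,
#'   (um^3 l^-1 h^-1) per (pmol Leu l^-1 h^-1).
#' @param conversion_noise_cv relative s.d. of the multiplicative noise on
#'   synthetic conversion pairs (default tuned so the through-origin
#'   regression shows r^2 of about 0.96).
#' @param incubation_h incubation duration (h) used for the halo chain.
#' @param n_active_cells active (halo-positive) cells scored per condition.
#' @param taxa named composition of probe labels for tolerant/philic cells.
#' @param sensitive_taxa composition used for piezosensitive cells
#'   (defaults weight the surface-derived, particle-associated taxa).
#' @param rate_atm_1000m,rate_atm_exp baseline atmospheric-pressure bulk
#'   rate profile `rate(z) = rate_atm_1000m * (z/1000)^rate_atm_exp`
#'   (pmol Leu l^-1 h^-1).
#' @param station_noise_sigma s.d. of the log10 station-to-station scatter
#'   of the atmospheric baseline.
#' @param npp net primary production handed to the budget generator
#'   (mg C m^-2 d^-1).
#' @param npp_noise_cv relative s.d. of NPP across stations.
#' @param volume_l,duration_h,specific_activity incubation metadata used
#'   when materializing scintillation counts (litres, hours, Ci mmol^-1).
#' @param n_live,n_killed live and killed-control replicates per bottle.
#' @param killed_fraction expected killed-control DPM as a fraction of the
#'   live expectation.
#'
#' @return An object of class `syn_config` (a validated list).
#' @export
#' @examples
#' cfg <- syn_config(seed = 1)
#' cfg$class_fractions
syn_config <- function(seed = 1L,
                       depths = c(150, 200, 300, 500, 750, 1000, 1250, 1500,
                                  2000, 2500, 3000, 3250, 3500, 4000),
                       n_stations_per_depth = 4L,
                       attenuation_coeff = 494,
                       attenuation_exp = -0.321,
                       ratio_noise_sigma = 0.1,
                       class_fractions = c(tolerant = 0.85, sensitive = 0.10,
                                           philic = 0.05),
                       base_log10_uptake_mu = -2.7,
                       base_log10_uptake_sigma = 0.5,
                       sensitive_fold_median = 150,
                       sensitive_fold_sigma = 0.15,
                       philic_fold_median = 0.1,
                       philic_fold_sigma = 0.15,
                       halo_noise_cv = 0.1,
                       conversion_slope = 9.72e7,
                       conversion_noise_cv = 0.2,
                       incubation_h = 10,
                       n_active_cells = 2000L,
                       taxa = c(SAR11 = 0.25, SAR202 = 0.18, SAR406 = 0.12,
                                Alteromonas = 0.05, Bacteroidetes = 0.05,
                                Thaumarchaeota = 0.22, Euryarchaeota = 0.13),
                       sensitive_taxa = c(SAR11 = 0.05, SAR202 = 0.02,
                                          SAR406 = 0.23, Alteromonas = 0.35,
                                          Bacteroidetes = 0.30,
                                          Thaumarchaeota = 0.02,
                                          Euryarchaeota = 0.03),
                       rate_atm_1000m = 0.42,
                       rate_atm_exp = -1.36,
                       station_noise_sigma = 0.08,
                       npp = 300,
                       npp_noise_cv = 0.1,
                       volume_l = 0.04,
                       duration_h = 10,
                       specific_activity = 110,
                       n_live = 3L,
                       n_killed = 2L,
                       killed_fraction = 0.05) {
  class_fractions <- stats::setNames(as.numeric(class_fractions),
                                     c("tolerant", "sensitive", "philic")[
                                       seq_along(class_fractions)])
  cfg <- structure(
    list(seed = as.integer(seed), depths = as.numeric(depths),
         n_stations_per_depth = as.integer(n_stations_per_depth),
         attenuation_coeff = attenuation_coeff,
         attenuation_exp = attenuation_exp,
         ratio_noise_sigma = ratio_noise_sigma,
         class_fractions = class_fractions,
         base_log10_uptake_mu = base_log10_uptake_mu,
         base_log10_uptake_sigma = base_log10_uptake_sigma,
         sensitive_fold_median = sensitive_fold_median,
         sensitive_fold_sigma = sensitive_fold_sigma,
         philic_fold_median = philic_fold_median,
         philic_fold_sigma = philic_fold_sigma,
         halo_noise_cv = halo_noise_cv,
         conversion_slope = conversion_slope,
         conversion_noise_cv = conversion_noise_cv,
         incubation_h = incubation_h,
         n_active_cells = as.integer(n_active_cells),
         taxa = taxa, sensitive_taxa = sensitive_taxa,
         rate_atm_1000m = rate_atm_1000m, rate_atm_exp = rate_atm_exp,
         station_noise_sigma = station_noise_sigma,
         npp = npp, npp_noise_cv = npp_noise_cv,
         volume_l = volume_l, duration_h = duration_h,
         specific_activity = specific_activity,
         n_live = as.integer(n_live), n_killed = as.integer(n_killed),
         killed_fraction = killed_fraction),
    class = "syn_config")
  validate_syn_config(cfg)
  cfg
}

validate_syn_config <- function(cfg) {
  stopifnot(inherits(cfg, "syn_config"))
  fr <- cfg$class_fractions
  if (length(fr) != 3L || any(fr < 0) || abs(sum(fr) - 1) > 1e-9)
    stop("class_fractions must be 3 non-negative values summing to 1",
         call. = FALSE)
  if (length(cfg$depths) < 1L || any(cfg$depths <= 0))
    stop("depths must be a non-empty list of positive metres", call. = FALSE)
  if (cfg$n_stations_per_depth < 1L)
    stop("n_stations_per_depth must be >= 1", call. = FALSE)
  sig <- c(cfg$ratio_noise_sigma, cfg$base_log10_uptake_sigma,
           cfg$sensitive_fold_sigma, cfg$philic_fold_sigma,
           cfg$halo_noise_cv, cfg$station_noise_sigma, cfg$npp_noise_cv,
           cfg$conversion_noise_cv)
  if (any(sig < 0)) stop("all noise sigmas must be >= 0", call. = FALSE)
  if (cfg$sensitive_fold_median <= 1)
    stop("sensitive_fold_median must be > 1", call. = FALSE)
  if (cfg$philic_fold_median <= 0 || cfg$philic_fold_median >= 1)
    stop("philic_fold_median must lie in (0, 1)", call. = FALSE)
  if (cfg$n_active_cells < 1L)
    stop("n_active_cells must be >= 1", call. = FALSE)
  if (cfg$conversion_slope <= 0)
    stop("conversion_slope must be > 0", call. = FALSE)
  if (cfg$incubation_h <= 0 || cfg$duration_h <= 0 || cfg$volume_l <= 0 ||
      cfg$specific_activity <= 0)
    stop("incubation metadata must be positive", call. = FALSE)
  if (cfg$killed_fraction < 0 || cfg$killed_fraction >= 1)
    stop("killed_fraction must lie in [0, 1)", call. = FALSE)
  invisible(cfg)
}

#' @export
print.syn_config <- function(x, ...) {
  cat("<syn_config>\n")
  cat("  seed:", x$seed, "\n")
  cat("  stations:", length(x$depths), "depths x", x$n_stations_per_depth,
      "stations\n")
  cat(sprintf("  attenuation: P = %g * z^%g, sigma_log10 = %g\n",
              x$attenuation_coeff, x$attenuation_exp, x$ratio_noise_sigma))
  cat(sprintf("  classes (tol/sens/phil): %g/%g/%g\n",
              x$class_fractions[1], x$class_fractions[2],
              x$class_fractions[3]))
  invisible(x)
}

# expected net DPM for a rate in pmol Leu l^-1 h^-1
expected_net_dpm <- function(rate, volume_l, duration_h, specific_activity) {
  rate * volume_l * duration_h * 1e-9 * specific_activity * CI_TO_DPM
}

#' Generate paired bulk radiotracer incubations
#'
#' For each station x depth, draws an atmospheric-pressure baseline bulk
#' rate from a depth-decaying profile and an in-situ rate equal to the
#' atmospheric rate times the attenuation power law `a * z^b / 100` times
#' lognormal noise. Optionally materializes scintillation counts (DPM) per
#' replicate bottle with Poisson counting noise, so the radiotracer
#' inversion can be round-tripped.
#'
#' @param config a [syn_config()].
#' @param dpm if `TRUE` (default) attach Poisson-noised DPM replicates.
#' @return A list with `incubations` (one row per station x depth x
#'   condition, with DPM replicate columns when `dpm = TRUE`) and `truth`
#'   (one row per station x depth: true atmospheric and in-situ rates and
#'   the true ratio in percent).
#' @export
#' @examples
#' prof <- gen_bulk_profiles(syn_config(seed = 3, ratio_noise_sigma = 0))
#' head(prof$truth)
gen_bulk_profiles <- function(config, dpm = TRUE) {
  validate_syn_config(config)
  set.seed(config$seed)
  grid <- expand.grid(depth_m = config$depths,
                      station_i = seq_len(config$n_stations_per_depth),
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  station <- sprintf("st%02d_z%04d", grid$station_i, as.integer(grid$depth_m))
  z <- grid$depth_m

  rate_atm <- config$rate_atm_1000m * (z / 1000)^config$rate_atm_exp *
    10^stats::rnorm(n, 0, config$station_noise_sigma)
  frac <- config$attenuation_coeff * z^config$attenuation_exp / 100
  ratio_noise <- 10^stats::rnorm(n, 0, config$ratio_noise_sigma)
  rate_insitu <- rate_atm * frac * ratio_noise

  truth <- data.frame(station = station, depth_m = z,
                      rate_atm_true = rate_atm,
                      rate_insitu_true = rate_insitu,
                      ratio_true_percent = 100 * rate_insitu / rate_atm)

  one_cond <- function(rate, condition) {
    df <- data.frame(station = station, depth_m = z, condition = condition,
                     sa_ci_per_mmol = config$specific_activity,
                     volume_l = config$volume_l,
                     duration_h = config$duration_h)
    if (dpm) {
      net <- expected_net_dpm(rate, config$volume_l, config$duration_h,
                              config$specific_activity)
      bg <- config$killed_fraction * net
      for (i in seq_len(config$n_live))
        df[[paste0("dpm_live_", i)]] <- stats::rpois(n, net + bg)
      for (i in seq_len(config$n_killed))
        df[[paste0("dpm_killed_", i)]] <- stats::rpois(n, bg)
    }
    df
  }
  incub <- rbind(one_cond(rate_atm, "atmospheric"),
                 one_cond(rate_insitu, "in_situ"))
  incub <- incub[order(incub$station, incub$condition), ]
  rownames(incub) <- NULL
  list(incubations = incub, truth = truth)
}

#' Draw in-situ:atmospheric ratio points from the attenuation model
#'
#' Convenience sampler used for regression and depth-profile experiments:
#' returns `P = a * z^b * 10^N(0, sigma)` percent at the requested depths.
#'
#' @param config a [syn_config()].
#' @param depths depths (m) at which to draw; defaults to the config's
#'   station grid replicated `n_stations_per_depth` times.
#' @return data.frame with `depth_m` and `p_percent`.
#' @export
gen_ratio_points <- function(config, depths = NULL) {
  validate_syn_config(config)
  if (is.null(depths))
    depths <- rep(config$depths, each = config$n_stations_per_depth)
  stopifnot(all(depths > 0))
  p <- config$attenuation_coeff * depths^config$attenuation_exp *
    10^stats::rnorm(length(depths), 0, config$ratio_noise_sigma)
  data.frame(depth_m = depths, p_percent = p)
}

sample_taxa <- function(n, class, taxa, sensitive_taxa) {
  out <- character(n)
  sens <- class == "sensitive"
  if (any(sens))
    out[sens] <- sample(names(sensitive_taxa), sum(sens), replace = TRUE,
                        prob = sensitive_taxa)
  if (any(!sens))
    out[!sens] <- sample(names(taxa), sum(!sens), replace = TRUE, prob = taxa)
  out
}

draw_latent_cells <- function(n, config) {
  class <- sample(names(config$class_fractions), n, replace = TRUE,
                  prob = config$class_fractions)
  u_insitu <- 10^stats::rnorm(n, config$base_log10_uptake_mu,
                              config$base_log10_uptake_sigma)
  fold <- rep(1, n)
  sens <- class == "sensitive"
  phil <- class == "philic"
  fold[sens] <- 10^stats::rnorm(sum(sens), log10(config$sensitive_fold_median),
                                config$sensitive_fold_sigma)
  fold[phil] <- 10^stats::rnorm(sum(phil), log10(config$philic_fold_median),
                                config$philic_fold_sigma)
  data.frame(class = class, uptake_insitu = u_insitu, fold = fold,
             uptake_atm = u_insitu * fold,
             taxon = sample_taxa(n, class, config$taxa, config$sensitive_taxa))
}

#' Generate a paired single-cell community
#'
#' Emulates a paired microautoradiography sample: the in-situ and
#' depressurized (atmospheric) conditions are independently sampled filters,
#' never the same physical cells. Each sampled cell carries a latent in-situ
#' uptake from the base lognormal, a piezo class from `class_fractions`, and
#' a depressurization fold-change (tolerant: 1; sensitive: lognormal
#' `> 1`-median; philic: lognormal `< 1`-median). The uptake realized under
#' the cell's own condition is pushed through the inverse
#' microautoradiography chain (uptake -> halo volume -> halo area) with
#' multiplicative area noise.
#'
#' @param config a [syn_config()].
#' @param sample_id label attached to all cells (default "s1").
#' @param geometry halo geometry used for the area chain.
#' @return A list with `cells` (cell_id, sample_id, condition, taxon,
#'   halo_area_um2) and `truth` (latent class, in-situ and atmospheric
#'   uptakes and fold for every sampled cell).
#' @export
#' @examples
#' com <- gen_paired_community(syn_config(seed = 42, n_active_cells = 200))
#' table(com$truth$class, com$truth$condition)
gen_paired_community <- function(config, sample_id = "s1",
                                 geometry = c("hemisphere", "sphere")) {
  validate_syn_config(config)
  geometry <- match.arg(geometry)
  set.seed(config$seed)
  n <- config$n_active_cells

  res <- lapply(c("in_situ", "atmospheric"), function(cond) {
    lat <- draw_latent_cells(n, config)
    lat$condition <- cond
    u_obs <- if (cond == "in_situ") lat$uptake_insitu else lat$uptake_atm
    vol <- uptake_to_volume(u_obs, config$incubation_h, config$conversion_slope)
    area <- area_from_volume(vol, geometry)
    if (config$halo_noise_cv > 0) {
      sdl <- sqrt(log(1 + config$halo_noise_cv^2))
      area <- area * stats::rlnorm(n, -sdl^2 / 2, sdl)
    }
    lat$halo_area_um2 <- area
    lat
  })
  lat <- do.call(rbind, res)
  lat$cell_id <- sprintf("%s_%s_%05d", sample_id,
                         ifelse(lat$condition == "in_situ", "is", "at"),
                         seq_len(nrow(lat)))
  lat$sample_id <- sample_id
  cells <- lat[, c("cell_id", "sample_id", "condition", "taxon",
                   "halo_area_um2")]
  truth <- lat[, c("cell_id", "sample_id", "condition", "taxon", "class",
                   "uptake_insitu", "uptake_atm", "fold")]
  rownames(cells) <- rownames(truth) <- NULL
  list(cells = cells, truth = truth)
}

#' Generate depth-resolved carbon-budget inputs
#'
#' Returns one row per station x depth with an atmospheric-pressure bulk
#' leucine incorporation rate drawn from the baseline profile and a net
#' primary production value with mild lognormal scatter.
#'
#' @param config a [syn_config()].
#' @return data.frame with `station`, `depth_m`, `php_atm_pmol_l_h`,
#'   `npp_mg_c_m2_d`.
#' @export
gen_budget_inputs <- function(config) {
  validate_syn_config(config)
  set.seed(config$seed + 1L)
  grid <- expand.grid(depth_m = config$depths,
                      station_i = seq_len(config$n_stations_per_depth),
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  z <- grid$depth_m
  rate <- config$rate_atm_1000m * (z / 1000)^config$rate_atm_exp *
    10^stats::rnorm(n, 0, config$station_noise_sigma)
  sdl <- sqrt(log(1 + config$npp_noise_cv^2))
  npp <- config$npp * stats::rlnorm(n, -sdl^2 / 2, sdl)
  data.frame(station = sprintf("st%02d_z%04d", grid$station_i,
                               as.integer(z)),
             depth_m = z, php_atm_pmol_l_h = rate, npp_mg_c_m2_d = npp)
}

#' Generate synthetic halo-volume conversion pairs
#'
#' Draws paired observations of the bulk leucine incorporation rate and the
#' total silver-grain halo volume production rate: `R_halo =
#' conversion_slope * R_leu * noise`, with multiplicative lognormal noise of
#' relative s.d. `conversion_noise_cv` (the default of 0.2 yields a
#' through-origin r^2 of about 0.96).
#'
#' @param config a [syn_config()].
#' @param n number of pairs.
#' @return data.frame with `bulk_rate` (pmol Leu l^-1 h^-1) and
#'   `halo_volume_rate` (um^3 l^-1 h^-1).
#' @export
gen_conversion_pairs <- function(config, n = 30L) {
  validate_syn_config(config)
  set.seed(config$seed + 2L)
  bulk <- 10^stats::rnorm(n, -0.7, 0.5)
  noise <- if (config$conversion_noise_cv > 0) {
    sdl <- sqrt(log(1 + config$conversion_noise_cv^2))
    stats::rlnorm(n, -sdl^2 / 2, sdl)
  } else rep(1, n)
  data.frame(bulk_rate = bulk,
             halo_volume_rate = config$conversion_slope * bulk * noise)
}
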