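# Depth-resolved carbon budget: prokaryotic heterotrophic production (PHP)
# from leucine incorporation, prokaryotic carbon demand (PCD) from growth
# efficiency, and the particulate organic carbon potentially available from
# sinking flux (POC_a); plus the biomass and depressurization-demand
# arithmetic used to assess vertical transport of surface-derived cells.

C_MOLAR_MASS <- 12.011  # g C mol^-1

#' Prokaryotic heterotrophic production from a leucine rate
#'
#' `PHP = rate * 24 * (CF * 1000 / 12.011) / 1000` in umol C m^-3 d^-1:
#' pmol Leu l^-1 h^-1 equals nmol m^-3 h^-1, x24 gives per day, and the
#' leucine-to-carbon conversion factor CF (kg C mol^-1 leucine) divided by
#' the molar mass of carbon gives mol C per mol leucine.
#'
#' @param rate bulk leucine incorporation rate, pmol Leu l^-1 h^-1 (>= 0).
#' @param cf leucine-to-carbon conversion factor, kg C mol^-1 (default
#'   1.55; 0.44 is the low-end alternative).
#' @return PHP, umol C m^-3 d^-1.
#' @export
#' @examples
#' php_from_rate(1)        # 3.097
#' php_from_rate(1, 0.44)
php_from_rate <- function(rate, cf = 1.55) {
  if (any(rate < 0)) stop("rate must be >= 0", call. = FALSE)
  if (cf <= 0) stop("cf must be > 0", call. = FALSE)
  rate * 24 * (cf * 1000 / C_MOLAR_MASS) / 1000
}

#' Prokaryotic carbon demand
#'
#' `PCD = PHP / PGE`, where PGE is the prokaryotic growth efficiency.
#'
#' @param php production, umol C m^-3 d^-1.
#' @param pge growth efficiency, fraction in (0, 1].
#' @return PCD, umol C m^-3 d^-1.
#' @export
pcd <- function(php, pge) {
  if (any(pge <= 0) || any(pge > 1))
    stop("pge must lie in (0, 1]", call. = FALSE)
  php / pge
}

#' Growth efficiency by depth stratum
#'
#' 8% for mesopelagic depths and 3% for bathypelagic depths, with the
#' half-open strata `[200, 1000)` and `[1000, Inf)`; depths above 200 m
#' also receive the mesopelagic value.
#'
#' @param z depth(s), metres.
#' @param pge_meso,pge_bathy stratum defaults.
#' @return PGE fraction(s).
#' @export
pge_for_depth <- function(z, pge_meso = 0.08, pge_bathy = 0.03) {
  ifelse(z >= 1000, pge_bathy, pge_meso)
}

#' Particulate organic carbon potentially available at depth
#'
#' `POC_a = 0.2 * NPP^1.66 * z^-1.68` in mmol C m^-3 d^-1, an export-flux
#' attenuation model rescaled to daily volumetric supply. NPP is net
#' primary production in mg C m^-2 d^-1 and z is depth in metres.
#'
#' @param npp net primary production, mg C m^-2 d^-1 (>= 0).
#' @param z depth, metres (> 0).
#' @return POC_a, mmol C m^-3 d^-1.
#' @export
#' @examples
#' poc_available(500, 1000)  # 0.0551
poc_available <- function(npp, z) {
  if (any(npp < 0)) stop("npp must be >= 0", call. = FALSE)
  if (any(z <= 0)) stop("z must be > 0", call. = FALSE)
  0.2 * npp^1.66 * z^-1.68
}

#' Ratio of carbon demand to carbon supply
#'
#' `(PCD / 1000) / POC_a` (PCD in umol converted to mmol).
#'
#' @param pcd_umol PCD, umol C m^-3 d^-1.
#' @param poc_mmol POC_a, mmol C m^-3 d^-1 (> 0).
#' @return dimensionless ratio.
#' @export
pcd_poc_ratio <- function(pcd_umol, poc_mmol) {
  if (any(poc_mmol <= 0)) stop("poc_a must be > 0", call. = FALSE)
  (pcd_umol / 1000) / poc_mmol
}

#' Prokaryotic biomass from cell abundance
#'
#' `biomass = cells_per_ml * 1000 * content_fg * 1e-9` ug C l^-1.
#'
#' @param cells_per_ml prokaryotic abundance, cells ml^-1 (>= 0).
#' @param content_fg carbon content per cell, fg C (default 10).
#' @return biomass, ug C l^-1.
#' @export
#' @examples
#' biomass_from_abundance(2.9e4)  # 0.29
biomass_from_abundance <- function(cells_per_ml, content_fg = 10) {
  if (any(cells_per_ml < 0) || any(content_fg < 0))
    stop("inputs must be >= 0", call. = FALSE)
  cells_per_ml * 1000 * content_fg * 1e-9
}

#' Organic carbon demand of a depressurization activity increase
#'
#' Converts the difference between depressurized and in-situ bulk leucine
#' incorporation rates into the extra organic carbon required to fuel it:
#' `delta_rate * duration_h * (CF * 1000) * 1e-12 * 1e9 / growth_yield`
#' ng C l^-1 (pmol -> mol -> g C -> ng, divided by the growth yield).
#'
#' @param delta_rate rate difference, pmol Leu l^-1 h^-1 (>= 0).
#' @param cf leucine-to-carbon conversion factor, kg C mol^-1.
#' @param growth_yield fraction of assimilated carbon retained, (0, 1].
#' @param duration_h integration time, hours (default 24).
#' @return demand, ng C l^-1.
#' @export
#' @examples
#' depressurization_demand(0.029)  # 2.16
depressurization_demand <- function(delta_rate, cf = 1.55,
                                    growth_yield = 0.5, duration_h = 24) {
  if (any(delta_rate < 0)) stop("delta_rate must be >= 0", call. = FALSE)
  if (growth_yield <= 0 || growth_yield > 1)
    stop("growth_yield must lie in (0, 1]", call. = FALSE)
  if (duration_h <= 0) stop("duration_h must be > 0", call. = FALSE)
  delta_rate * duration_h * (cf * 1000) * 1e-12 * 1e9 / growth_yield
}

#' Depth-resolved carbon budget table
#'
#' One row per input row per conversion-factor scenario: PHP under
#' atmospheric pressure, PHP corrected to in-situ pressure with the depth
#' power law, PCD from the stratum growth efficiency, POC_a from NPP and
#' depth, and the PCD:POC_a ratio.
#'
#' @param inputs data.frame with `depth_m`, `php_atm_pmol_l_h`,
#'   `npp_mg_c_m2_d` (a `station` column is carried through).
#' @param fit `power_law_fit` used for the in-situ correction.
#' @param cf conversion-factor scenarios, kg C mol^-1.
#' @param correct_insitu apply the pressure correction (default TRUE).
#' @param cap_at_100 passed to [predict_fraction()].
#' @return data.frame of budget rows with columns `depth_m`, `cf`,
#'   `php_atm`, `php_insitu` (umol C m^-3 d^-1), `pge`, `pcd_umol_m3_d`,
#'   `npp`, `poc_a_mmol_m3_d`, `ratio_pcd_poc`.
#' @export
carbon_budget <- function(inputs, fit = power_law(494, -0.321),
                          cf = c(1.55, 0.44), correct_insitu = TRUE,
                          cap_at_100 = TRUE) {
  stopifnot(all(c("depth_m", "php_atm_pmol_l_h", "npp_mg_c_m2_d") %in%
                  names(inputs)))
  rows <- lapply(cf, function(f) {
    php_atm <- php_from_rate(inputs$php_atm_pmol_l_h, f)
    php_insitu <- if (correct_insitu)
      correct_php(php_atm, inputs$depth_m, fit, cap_at_100) else php_atm
    pge <- pge_for_depth(inputs$depth_m)
    pcd_v <- pcd(php_insitu, pge)
    poc <- poc_available(inputs$npp_mg_c_m2_d, inputs$depth_m)
    data.frame(station = if (!is.null(inputs$station)) inputs$station else
                 NA_character_,
               depth_m = inputs$depth_m, cf = f,
               php_atm = php_atm, php_insitu = php_insitu, pge = pge,
               pcd_umol_m3_d = pcd_v, npp = inputs$npp_mg_c_m2_d,
               poc_a_mmol_m3_d = poc,
               ratio_pcd_poc = pcd_poc_ratio(pcd_v, poc))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
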