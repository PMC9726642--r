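# File-based orchestration: simulate a synthetic dataset, analyze a dataset
# directory end-to-end, and run the simulate-then-analyze recovery loop.
# Every run writes a manifest (config snapshot, seeds, file digests,
# timings, package version) from which the outputs can be regenerated.

write_manifest <- function(dir, config, seed, extra = list()) {
  files <- setdiff(list.files(dir), "manifest.json")
  digests <- as.list(tools::md5sum(file.path(dir, files)))
  names(digests) <- files
  manifest <- c(list(
    package = "piezoprod",
    version = as.character(utils::packageVersion("piezoprod")),
    seed = seed,
    config = unclass(config),
    files = digests), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a complete synthetic dataset to disk
#'
#' Runs all three generators and writes `incubations.csv`, `cells.csv`,
#' `budget_inputs.csv`, the latent truth tables (`truth_rates.csv`,
#' `truth_cells.csv`), the config snapshot (`config.yaml`) and a run
#' manifest.
#'
#' @param config a [syn_config()]; may also be the path of a YAML file with
#'   `syn_config` arguments.
#' @param out_dir output directory (created if missing).
#' @param n_communities number of paired microautoradiography samples to
#'   simulate (each uses `n_active_cells` per condition).
#' @return `out_dir`, invisibly.
#' @export
pp_simulate <- function(config = syn_config(), out_dir, n_communities = 6L) {
  if (is.character(config)) config <- do.call(syn_config, yaml::read_yaml(config))
  validate_syn_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  prof <- gen_bulk_profiles(config)
  utils::write.csv(prof$incubations, file.path(out_dir, "incubations.csv"),
                   row.names = FALSE)
  utils::write.csv(prof$truth, file.path(out_dir, "truth_rates.csv"),
                   row.names = FALSE)

  coms <- lapply(seq_len(n_communities), function(i) {
    cfg_i <- config
    cfg_i$seed <- config$seed + 100L + i
    gen_paired_community(cfg_i, sample_id = sprintf("s%02d", i))
  })
  cells <- do.call(rbind, lapply(coms, `[[`, "cells"))
  truth <- do.call(rbind, lapply(coms, `[[`, "truth"))
  utils::write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(truth, file.path(out_dir, "truth_cells.csv"),
                   row.names = FALSE)

  utils::write.csv(gen_budget_inputs(config),
                   file.path(out_dir, "budget_inputs.csv"), row.names = FALSE)

  cfg_out <- unclass(config)
  cfg_out$class_fractions <- as.list(config$class_fractions)
  cfg_out$taxa <- as.list(config$taxa)
  cfg_out$sensitive_taxa <- as.list(config$sensitive_taxa)
  yaml::write_yaml(cfg_out, file.path(out_dir, "config.yaml"))

  write_manifest(out_dir, config, config$seed,
                 list(stage = "simulate", n_communities = n_communities,
                      elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs"))))
  invisible(out_dir)
}

#' Analyze a dataset directory end-to-end
#'
#' Reads the `pp_simulate()` file layout (or equivalently formatted real
#' tables) and runs the full chain: rates -> ratio points -> power-law fit;
#' halo areas -> uptake -> histograms -> piezo classification -> taxon
#' tests; budget inputs -> carbon budget. Writes `rates.csv`,
#' `ratios.csv`, `fit.json`, `cell_uptake.csv`, `histograms.json`,
#' `classification.json`, `taxon_tests.csv`, `budget.csv`, a markdown
#' summary `report.md` and a manifest.
#'
#' @param data_dir directory with the input tables.
#' @param out_dir results directory (created if missing).
#' @param cf conversion-factor scenarios for the budget.
#' @param geometry halo geometry.
#' @param width histogram bin width (log10 units).
#' @param duration_h incubation duration used for the uptake chain; by
#'   default taken from `config.yaml` in `data_dir` when present, else 10.
#' @param conversion_slope halo-volume conversion slope; default from
#'   `config.yaml` when present, else 9.72e7.
#' @param cap_at_100 cap the pressure correction at 100%.
#' @return Invisibly, a list with the main fitted objects.
#' @export
pp_analyze <- function(data_dir, out_dir, cf = c(1.55, 0.44),
                       geometry = c("hemisphere", "sphere"), width = 0.17,
                       duration_h = NULL, conversion_slope = NULL,
                       cap_at_100 = TRUE) {
  geometry <- match.arg(geometry)
  need <- c("incubations.csv", "cells.csv", "budget_inputs.csv")
  missing_f <- need[!file.exists(file.path(data_dir, need))]
  if (length(missing_f))
    stop("missing input file(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  cfg_path <- file.path(data_dir, "config.yaml")
  cfg <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else list()
  if (is.null(duration_h)) duration_h <- cfg$incubation_h %||2% 10
  if (is.null(conversion_slope))
    conversion_slope <- cfg$conversion_slope %||2% 9.72e7

  # --- bulk chain ---
  incub <- utils::read.csv(file.path(data_dir, "incubations.csv"))
  rates <- rates_from_incubations(incub)
  utils::write.csv(rates, file.path(out_dir, "rates.csv"), row.names = FALSE)
  ratios <- ratio_points_from_rates(rates)
  utils::write.csv(ratios, file.path(out_dir, "ratios.csv"),
                   row.names = FALSE)
  fit <- fit_power_law(ratios)
  jsonlite::write_json(
    list(a = fit$a, b = fit$b, r2 = fit$r2, n = fit$n,
         se = as.list(fit$se),
         ci = list(b = fit$ci$b, a = 10^fit$ci$log10_a),
         sigma = fit$sigma),
    file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)

  # --- single-cell chain ---
  cells <- utils::read.csv(file.path(data_dir, "cells.csv"))
  if (is.null(cells$sample_id)) cells$sample_id <- "s1"
  ut <- cell_uptake_table(cells, duration_h, conversion_slope, geometry)
  utils::write.csv(ut[, c("cell_id", "sample_id", "condition", "taxon",
                          "uptake_amol_d")],
                   file.path(out_dir, "cell_uptake.csv"), row.names = FALSE)
  act <- ut[ut$active, ]
  u_in <- act$uptake_amol_d[act$condition == "in_situ"]
  u_at <- act$uptake_amol_d[act$condition == "atmospheric"]
  hists <- build_paired_histograms(u_in, u_at, width)
  jsonlite::write_json(
    lapply(hists, function(h) list(edges = h$edges, counts = h$counts,
                                   n_active = h$n_active, width = h$width,
                                   anchor = h$anchor)),
    file.path(out_dir, "histograms.json"), digits = NA, auto_unbox = TRUE)
  cls <- classify_piezo(hists$in_situ, hists$atmospheric)
  ha <- highly_active_fraction(u_at)
  jsonlite::write_json(
    list(tolerant = cls$tolerant,
         sensitive = list(min = cls$sensitive_min, max = cls$sensitive_max,
                          mid = cls$sensitive_mid),
         philic = list(min = cls$philic_min, max = cls$philic_max,
                       mid = cls$philic_mid),
         moved_mass = cls$m, width = cls$width, anchor = cls$anchor,
         highly_active_fraction_atm = ha$fraction),
    file.path(out_dir, "classification.json"), auto_unbox = TRUE,
    digits = NA)
  tt <- taxon_tests(act)
  utils::write.csv(tt, file.path(out_dir, "taxon_tests.csv"),
                   row.names = FALSE)

  # --- budget chain ---
  binp <- utils::read.csv(file.path(data_dir, "budget_inputs.csv"))
  budget <- carbon_budget(binp, fit = fit, cf = cf,
                          cap_at_100 = cap_at_100)
  utils::write.csv(budget, file.path(out_dir, "budget.csv"),
                   row.names = FALSE)

  writeLines(c(
    "# Analysis report", "",
    sprintf("- power law: P = %.1f * z^%.3f (n = %d, r2 = %.3f)",
            fit$a, fit$b, fit$n, fit$r2),
    sprintf("- piezotolerant: %.1f%% of active cells", 100 * cls$tolerant),
    sprintf("- piezosensitive: %.1f%% [%.1f, %.1f]",
            100 * cls$sensitive_mid, 100 * cls$sensitive_min,
            100 * cls$sensitive_max),
    sprintf("- piezophilic: %.1f%% [%.1f, %.1f]", 100 * cls$philic_mid,
            100 * cls$philic_min, 100 * cls$philic_max),
    sprintf("- highly active (>0.5 amol d^-1), atmospheric: %.2f%%",
            100 * ha$fraction),
    sprintf("- median PCD:POC ratio (cf = %.2f, bathypelagic): %.2f",
            cf[1], stats::median(
              budget$ratio_pcd_poc[budget$cf == cf[1] &
                                     budget$depth_m >= 1000])),
    "",
    sprintf("Parameters: bin width %.2f (log10), geometry %s, duration %g h,",
            width, geometry, duration_h),
    sprintf("conversion slope %.3g, CF scenarios {%s}.",
            conversion_slope, paste(cf, collapse = ", "))),
    file.path(out_dir, "report.md"))

  write_manifest(out_dir, structure(cfg, class = "list"), cfg$seed %||2% NA,
                 list(stage = "analyze",
                      params = list(cf = cf, geometry = geometry,
                                    width = width, duration_h = duration_h,
                                    conversion_slope = conversion_slope),
                      elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs"))))
  invisible(list(fit = fit, classification = cls, budget = budget,
                 taxon_tests = tt, highly_active = ha))
}

# default-or helper tolerant of NULLs from yaml
`%||2%` <- function(a, b) if (is.null(a)) b else a

#' Simulate-then-analyze recovery check
#'
#' Generates a dataset with `config`, analyzes it, and compares the
#' recovered attenuation coefficients, class-fraction midpoints and
#' conversion slope with the generator truth.
#'
#' @param config a [syn_config()].
#' @param tol_b relative tolerance on the recovered exponent.
#' @param tol_fraction absolute tolerance on recovered class fractions.
#' @param dir working directory (default a tempdir).
#' @return list with `recovered`, `truth`, `pass` (named logicals).
#' @export
pp_recover <- function(config = syn_config(), tol_b = 0.15,
                       tol_fraction = 0.05, dir = tempfile("pp_recover_")) {
  data_dir <- file.path(dir, "data"); out_dir <- file.path(dir, "results")
  pp_simulate(config, data_dir)
  res <- pp_analyze(data_dir, out_dir)
  fit <- res$fit; cls <- res$classification
  recovered <- list(a = fit$a, b = fit$b,
                    tolerant = cls$tolerant,
                    sensitive = cls$sensitive_mid,
                    philic = cls$philic_mid)
  truth <- list(a = config$attenuation_coeff, b = config$attenuation_exp,
                tolerant = unname(config$class_fractions[1]),
                sensitive = unname(config$class_fractions[2]),
                philic = unname(config$class_fractions[3]))
  pass <- c(
    b_rel = abs(fit$b - truth$b) <= tol_b * abs(truth$b),
    b_in_ci = truth$b >= fit$ci$b[1] && truth$b <= fit$ci$b[2],
    a_in_ci = log10(truth$a) >= fit$ci$log10_a[1] &&
      log10(truth$a) <= fit$ci$log10_a[2],
    tolerant = abs(cls$tolerant - truth$tolerant) <= tol_fraction,
    sensitive = abs(cls$sensitive_mid - truth$sensitive) <= tol_fraction,
    philic = abs(cls$philic_mid - truth$philic) <= tol_fraction)
  list(recovered = recovered, truth = truth, pass = pass, dir = dir)
}
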