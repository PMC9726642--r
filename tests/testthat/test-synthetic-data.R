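test_that("config validation rejects impossible study designs", {
  expect_s3_class(syn_config(), "syn_config")
  expect_error(syn_config(class_fractions = c(0.5, 0.4, 0.2)), "summing to 1")
  expect_error(syn_config(class_fractions = c(1.2, -0.1, -0.1)))
  expect_error(syn_config(depths = numeric(0)), "depths")
  expect_error(syn_config(depths = c(100, -5)), "depths")
  expect_error(syn_config(n_stations_per_depth = 0), "n_stations")
  expect_error(syn_config(sensitive_fold_median = 0.9), "sensitive_fold")
  expect_error(syn_config(philic_fold_median = 1.5), "philic_fold")
  expect_error(syn_config(ratio_noise_sigma = -0.1), "sigma")
  expect_error(syn_config(n_active_cells = 0), "n_active_cells")
})

test_that("noiseless bulk profiles reproduce the attenuation law exactly", {
  cfg <- syn_config(seed = 1, ratio_noise_sigma = 0,
                    depths = c(1, 4000), n_stations_per_depth = 2)
  prof <- gen_bulk_profiles(cfg, dpm = FALSE)
  tr <- prof$truth
  # z = 1: ratio equals the coefficient a; z = 4000: direct evaluation
  expect_equal(tr$ratio_true_percent[tr$depth_m == 1], rep(494, 2))
  expect_equal(tr$ratio_true_percent[tr$depth_m == 4000],
               rep(494 * 4000^-0.321, 2), tolerance = 1e-12)
  expect_equal(494 * 4000^-0.321, 34.5, tolerance = 0.002)
})

test_that("generators are deterministic under a fixed seed and vary across seeds", {
  cfg <- syn_config(seed = 9, n_active_cells = 100)
  p1 <- gen_bulk_profiles(cfg)
  p2 <- gen_bulk_profiles(cfg)
  expect_identical(p1, p2)
  c1 <- gen_paired_community(cfg)
  c2 <- gen_paired_community(cfg)
  expect_identical(c1, c2)
  b1 <- gen_budget_inputs(cfg)
  expect_identical(b1, gen_budget_inputs(cfg))
  cfg2 <- syn_config(seed = 10, n_active_cells = 100)
  expect_false(identical(gen_bulk_profiles(cfg2)$truth$rate_atm_true,
                         p1$truth$rate_atm_true))
  expect_false(identical(gen_paired_community(cfg2)$cells$halo_area_um2,
                         c1$cells$halo_area_um2))
})

test_that("killed-control DPM stay below live DPM", {
  prof <- gen_bulk_profiles(syn_config(seed = 4))
  inc <- prof$incubations
  live <- rowMeans(inc[, grep("^dpm_live_", names(inc))])
  killed <- rowMeans(inc[, grep("^dpm_killed_", names(inc))])
  expect_true(all(killed < live))
})

test_that("forced fold-changes propagate exactly to the latent table", {
  # tolerant-only community: atmospheric law identical to in-situ law
  cfg <- syn_config(seed = 2, class_fractions = c(1, 0, 0),
                    halo_noise_cv = 0, n_active_cells = 300)
  com <- gen_paired_community(cfg)
  expect_true(all(com$truth$fold == 1))
  expect_equal(com$truth$uptake_atm, com$truth$uptake_insitu)

  # all-sensitive community with a degenerate fold distribution
  cfg2 <- syn_config(seed = 2, class_fractions = c(0, 1, 0),
                     sensitive_fold_median = 100, sensitive_fold_sigma = 0,
                     halo_noise_cv = 0, n_active_cells = 300)
  com2 <- gen_paired_community(cfg2)
  expect_equal(com2$truth$uptake_atm, 100 * com2$truth$uptake_insitu)
})

test_that("latent class fractions match the configuration within binomial error", {
  cfg <- syn_config(seed = 31, n_active_cells = 4000)
  com <- gen_paired_community(cfg)
  frac <- prop.table(table(com$truth$class))
  # 4 sd binomial bands around the configured mixture
  for (cl in c("tolerant", "sensitive", "philic")) {
    p <- cfg$class_fractions[[cl]]
    expect_lt(abs(frac[[cl]] - p), 4 * sqrt(p * (1 - p) / 8000) + 1e-12)
  }
})

test_that("sensitive-cell fold changes sit near the configured median", {
  cfg <- syn_config(seed = 8, n_active_cells = 3000)
  com <- gen_paired_community(cfg)
  tr <- com$truth[com$truth$class == "sensitive", ]
  expect_gt(mean(tr$uptake_atm / tr$uptake_insitu),
            cfg$sensitive_fold_median / 2)
})

test_that("budget inputs are positive and PHP of zero gives zero demand", {
  binp <- gen_budget_inputs(syn_config(seed = 3))
  expect_true(all(binp$php_atm_pmol_l_h > 0))
  expect_true(all(binp$npp_mg_c_m2_d > 0))
  binp$php_atm_pmol_l_h <- 0
  bud <- carbon_budget(binp)
  expect_true(all(bud$pcd_umol_m3_d == 0))
})

test_that("conversion pairs carry the configured slope and noise level", {
  cfg <- syn_config(seed = 5, conversion_noise_cv = 0)
  pairs <- gen_conversion_pairs(cfg, n = 10)
  expect_equal(pairs$halo_volume_rate, 9.72e7 * pairs$bulk_rate)
  cfg2 <- syn_config(seed = 5)
  pairs2 <- gen_conversion_pairs(cfg2, n = 500)
  fit <- fit_conversion(pairs2$bulk_rate, pairs2$halo_volume_rate)
  expect_gt(fit$r2, 0.90)
  expect_lt(fit$r2, 0.99)
})
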