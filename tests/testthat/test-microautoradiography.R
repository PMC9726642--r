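test_that("halo volume follows the (hemi)sphere geometry", {
  expect_equal(halo_volume(0), 0)
  expect_equal(halo_volume(pi), 2 * pi / 3)
  expect_equal(halo_volume(pi, "sphere"), 4 * pi / 3)
  expect_error(halo_volume(-1), "area")
  # inverse chain
  a <- c(0, 0.3, 2, 40)
  expect_equal(area_from_volume(halo_volume(a)), a)
  expect_equal(area_from_volume(halo_volume(a, "sphere"), "sphere"), a)
})

test_that("conversion fit reproduces the through-origin slope", {
  expect_equal(fit_conversion(1, 9.72e7)$slope, 9.72e7)
  x <- c(0.05, 0.2, 0.7, 1.3)
  f <- fit_conversion(x, 9.72e7 * x)
  expect_equal(f$slope, 9.72e7)
  expect_equal(f$r2, 1)
  expect_error(fit_conversion(c(0, 0), c(1, 2)), "zero")
})

test_that("noisy conversion pairs recover the slope within 5% at r2 near 0.96", {
  slopes <- sapply(1:10, function(s) {
    pairs <- gen_conversion_pairs(syn_config(seed = s), n = 30)
    fit_conversion(pairs$bulk_rate, pairs$halo_volume_rate)$slope
  })
  expect_lt(abs(mean(slopes) / 9.72e7 - 1), 0.05)
})

test_that("cell uptake matches the dimensional conversion and its symmetries", {
  expect_equal(cell_uptake(0, 10, 9.72e7), 0)
  expect_equal(cell_uptake(40.5, 10, 9.72e7), 1.00, tolerance = 1e-9)
  expect_equal(cell_uptake(81, 10, 9.72e7), 2 * cell_uptake(40.5, 10, 9.72e7))
  expect_equal(cell_uptake(40.5, 20, 9.72e7), 0.5)
  expect_error(cell_uptake(40.5, 0, 9.72e7), "duration")
  # inverse chain
  u <- c(0.01, 0.5, 3)
  expect_equal(cell_uptake(uptake_to_volume(u, 10, 9.72e7), 10, 9.72e7), u)
})

test_that("uptake is invariant to the halo geometry when conversion and cells share it", {
  cfg <- syn_config(seed = 6, n_active_cells = 200, halo_noise_cv = 0)
  for (geom in c("hemisphere", "sphere")) {
    com <- gen_paired_community(cfg, geometry = geom)
    ut <- cell_uptake_table(com$cells, cfg$incubation_h,
                            cfg$conversion_slope, geometry = geom)
    obs_truth <- ifelse(com$truth$condition == "in_situ",
                        com$truth$uptake_insitu, com$truth$uptake_atm)
    expect_equal(ut$uptake_amol_d, obs_truth, tolerance = 1e-9)
  }
  # scaling all volumes by a constant cancels after refitting the conversion
  vol <- c(1, 5, 20)
  bulk <- c(0.1, 0.5, 2)
  f1 <- fit_conversion(bulk, vol)
  f2 <- fit_conversion(bulk, 2 * vol)
  expect_equal(cell_uptake(vol, 10, f1), cell_uptake(2 * vol, 10, f2))
})

test_that("histograms follow the half-open fixed-width convention", {
  h <- build_histogram(rep(1, 10), width = 0.17)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(sum(h$counts), 10)
  # a value exactly on an edge falls in the bin above
  h2 <- build_histogram(c(10^0.17, 10^0.17, 10^0.3), width = 0.17, anchor = 0)
  expect_equal(h2$counts, c(0, 3))
  expect_equal(diff(h2$edges), rep(0.17, 2))
  expect_error(build_histogram(numeric(0)), "no active")
  expect_error(build_histogram(c(1, 0)), "positive")
  # paired histograms share edges and conserve counts
  com <- gen_paired_community(syn_config(seed = 13, n_active_cells = 400))
  u <- latent_uptakes(com)
  hp <- build_paired_histograms(u$in_situ, u$atm)
  expect_identical(hp$in_situ$edges, hp$atmospheric$edges)
  expect_equal(sum(hp$in_situ$counts), 400)
  expect_equal(sum(hp$atmospheric$counts), 400)
})

test_that("bin width rules return their closed forms", {
  expect_equal(bin_width(rnorm(10), "fixed"), 0.17)
  set.seed(1)
  x <- rnorm(5000)
  expect_equal(bin_width(x, "scott"), 3.49 * sd(x) * 5000^(-1 / 3))
  expect_equal(bin_width(x, "freedman_diaconis"),
               2 * IQR(x) * 5000^(-1 / 3))
  expect_error(bin_width(1, "scott"), "n >= 2")
})

test_that("cost-minimizing bin width behaves like the known optima", {
  set.seed(2)
  # for a uniform density wider bins only reduce variance: the cost picks
  # the widest candidate
  u <- runif(5000)
  h_u <- bin_width(u, "shimazaki", n_candidates = 50)
  expect_gt(h_u, diff(range(u)) / 3)
  # for a Gaussian the cost minimum sits near the MISE-optimal width
  # (Scott's rule); agreement within a factor of 2 at this n
  x <- rnorm(5000)
  h_g <- bin_width(x, "shimazaki", n_candidates = 200)
  expect_gt(h_g / bin_width(x, "scott"), 0.5)
  expect_lt(h_g / bin_width(x, "scott"), 2)
})

test_that("highly active counting uses a strict threshold", {
  expect_equal(highly_active_fraction(c(0.1, 0.2))$count, 0)
  res <- highly_active_fraction(c(0.4, 0.5, 0.6))
  expect_equal(res$count, 1)
  expect_equal(res$fraction, 1 / 3)
  expect_error(highly_active_fraction(numeric(0)), "no uptake")
})

test_that("paired taxon tests select the test from the normality of differences", {
  set.seed(5)
  # normal shift: paired t chosen, small p for a real effect
  ins <- rnorm(15, 1, 0.1)
  r_t <- taxon_paired_test(ins, ins + 0.5 + rnorm(15, 0, 0.1),
                           taxon = "x", alternative = "greater")
  expect_equal(r_t$test_used, "paired_t")
  expect_lt(r_t$p, 0.001)
  # heavy-tailed differences: Wilcoxon chosen
  d <- rcauchy(30)
  r_w <- taxon_paired_test(rep(1, 30), 1 + d, taxon = "y")
  expect_equal(r_w$test_used, "wilcoxon_signed_rank")
  # identical pairs are degenerate
  r_d <- taxon_paired_test(ins, ins)
  expect_true(r_d$degenerate)
  expect_true(is.na(r_d$p))
  expect_error(taxon_paired_test(1:2, 2:3), "3 pairs")
})

test_that("taxon test table detects the piezosensitive taxa in a simulated study", {
  coms <- lapply(1:6, function(i) {
    cfg <- syn_config(seed = 400 + i, n_active_cells = 400)
    gen_paired_community(cfg, sample_id = sprintf("s%02d", i))
  })
  cells <- do.call(rbind, lapply(coms, `[[`, "cells"))
  ut <- cell_uptake_table(cells, 10, 9.72e7)
  tt <- taxon_tests(ut[ut$active, ], alternative = "greater")
  # Alteromonas and Bacteroidetes carry most of the sensitive mass
  expect_lt(tt$p[tt$taxon == "Alteromonas"], 0.05)
  expect_lt(tt$p[tt$taxon == "Bacteroidetes"], 0.05)
  # Thaumarchaeota are drawn almost entirely from the tolerant pool
  expect_gt(tt$p[tt$taxon == "Thaumarchaeota"], 0.05)
})
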