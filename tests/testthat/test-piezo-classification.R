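mk_hist <- function(counts, width = 0.17, anchor = 0) {
  structure(list(edges = anchor + width * (0:length(counts)),
                 counts = counts, n_active = sum(counts),
                 width = width, anchor = anchor),
            class = "activity_histogram")
}

test_that("histogram intersection matches hand-computed minima", {
  # p_in = {0.6, 0.4, 0}, p_atm = {0.5, 0, 0.5}
  mt <- match_tolerant(mk_hist(c(6, 4, 0)), mk_hist(c(5, 0, 5)))
  expect_equal(mt$tolerant, 0.5)
  expect_equal(mt$residual_in, c(0.1, 0.4, 0))
  expect_equal(mt$residual_atm, c(0, 0, 0.5))
  expect_equal(mt$m, 0.5)
  # identical histograms
  mt2 <- match_tolerant(mk_hist(c(3, 7)), mk_hist(c(3, 7)))
  expect_equal(mt2$tolerant, 1)
  expect_equal(sum(mt2$residual_in), 0)
  # disjoint histograms
  mt3 <- match_tolerant(mk_hist(c(5, 0)), mk_hist(c(0, 5)))
  expect_equal(mt3$tolerant, 0)
  expect_equal(mt3$m, 1)
  expect_error(match_tolerant(mk_hist(c(1, 1)), mk_hist(c(1, 1), anchor = 1)),
               "identical bin edges")
})

test_that("transport bounds match forced-move hand computations", {
  b0 <- transport_bounds(rep(0, 3), rep(0, 3))
  expect_equal(unlist(b0[1:4]), c(up_min = 0, up_max = 0, down_min = 0,
                                  down_max = 0))
  # single forced upward move b1 -> b3
  b1 <- transport_bounds(c(0.2, 0, 0), c(0, 0, 0.2))
  expect_equal(b1$up_min, 0.2)
  expect_equal(b1$up_max, 0.2)
  expect_equal(b1$down_min, 0)
  expect_equal(b1$down_max, 0)
  # b1 -> b3 up and b5 -> b3 down, both forced
  b2 <- transport_bounds(c(0.1, 0, 0, 0, 0.1), c(0, 0, 0.2, 0, 0))
  expect_equal(c(b2$up_min, b2$up_max), c(0.1, 0.1))
  expect_equal(c(b2$down_min, b2$down_max), c(0.1, 0.1))
  expect_error(transport_bounds(c(0.5, 0), c(0, 0.2)), "totals differ")
})

test_that("transport bounds equal the exhaustive enumeration oracle", {
  set.seed(99)
  for (i in 1:40) {
    rp <- random_residual_pair(n_bins = sample(2:5, 1),
                               total_units = sample(2:6, 1))
    oracle <- enumerate_transport_range(rp$units_in, rp$units_atm)
    tb <- transport_bounds(rp$units_in / 10, rp$units_atm / 10)
    expect_equal(tb$up_min, oracle$up[1] / 10, tolerance = 1e-12)
    expect_equal(tb$up_max, oracle$up[2] / 10, tolerance = 1e-12)
    expect_equal(tb$down_min, oracle$down[1] / 10, tolerance = 1e-12)
    expect_equal(tb$down_max, oracle$down[2] / 10, tolerance = 1e-12)
  }
  # overlapping supports violate the classifier's precondition
  expect_error(transport_bounds(c(0.3, 0.3), c(0.3, 0.3)), "disjoint")
})

test_that("classification satisfies its sum rules on randomized histograms", {
  set.seed(17)
  for (i in 1:25) {
    nb <- sample(3:8, 1)
    h1 <- mk_hist(rpois(nb, 5) + 1)
    h2 <- mk_hist(rpois(nb, 5) + 1)
    cl <- classify_piezo(h1, h2)
    expect_equal(cl$m, 1 - cl$tolerant, tolerance = 1e-9)
    expect_lte(cl$sensitive_min, cl$sensitive_max + 1e-12)
    expect_lte(cl$philic_min, cl$philic_max + 1e-12)
    expect_equal(cl$sensitive_min + cl$philic_max, cl$m, tolerance = 1e-9)
    expect_equal(cl$sensitive_max + cl$philic_min, cl$m, tolerance = 1e-9)
  }
})

test_that("swapping conditions swaps sensitive and philic bounds exactly", {
  set.seed(23)
  h1 <- mk_hist(rpois(6, 4) + 1)
  h2 <- mk_hist(rpois(6, 4) + 1)
  ab <- classify_piezo(h1, h2)
  ba <- classify_piezo(h2, h1)
  expect_equal(ab$sensitive_min, ba$philic_min)
  expect_equal(ab$sensitive_max, ba$philic_max)
  expect_equal(ab$tolerant, ba$tolerant)
})

test_that("shifting both anchors by a multiple of the width changes nothing", {
  com <- gen_paired_community(syn_config(seed = 3, n_active_cells = 500))
  u <- latent_uptakes(com)
  h <- build_paired_histograms(u$in_situ, u$atm)
  cl1 <- classify_piezo(h$in_situ, h$atmospheric)
  shift <- function(hst, k) {
    hst$anchor <- hst$anchor - k * hst$width
    hst$counts <- c(rep(0L, k), hst$counts)
    hst$edges <- hst$anchor + hst$width * (0:length(hst$counts))
    hst
  }
  cl2 <- classify_piezo(shift(h$in_situ, 3), shift(h$atmospheric, 3))
  expect_equal(cl1$tolerant, cl2$tolerant)
  expect_equal(cl1$sensitive_mid, cl2$sensitive_mid)
  expect_equal(cl1$philic_mid, cl2$philic_mid)
})

test_that("a noise-free tolerant-only community classifies as 100% tolerant", {
  cfg <- syn_config(seed = 2, class_fractions = c(1, 0, 0),
                    halo_noise_cv = 0, n_active_cells = 500)
  com <- gen_paired_community(cfg)
  # identical latent law and zero noise: use the same draw on both sides
  u_in <- com$truth$uptake_insitu[com$truth$condition == "in_situ"]
  cl <- classify_piezo_uptakes(u_in, u_in)
  expect_equal(cl$tolerant, 1)
  expect_equal(cl$sensitive_mid, 0)
  expect_equal(cl$philic_mid, 0)
})

test_that("the classifier recovers the generated community composition", {
  cls <- lapply(1:5, function(s) {
    com <- gen_paired_community(syn_config(seed = 40 + s))
    u <- latent_uptakes(com)
    classify_piezo_uptakes(u$in_situ, u$atm)
  })
  tol <- mean(sapply(cls, `[[`, "tolerant"))
  sen <- mean(sapply(cls, `[[`, "sensitive_mid"))
  phi <- mean(sapply(cls, `[[`, "philic_mid"))
  expect_lt(abs(tol - 0.85), 0.05)
  expect_lt(abs(sen - 0.10), 0.05)
  expect_lt(abs(phi - 0.05), 0.05)
})
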