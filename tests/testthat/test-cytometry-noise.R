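# Flow-cytometry gating pipeline and noise estimators.

test_that("time trimming drops the unstable acquisition windows", {
  ev <- data.frame(time = seq(0, 11.9, by = 0.1), fsc = 50000, ssc = 50000,
                   gfp = 100)
  out <- trim_time(ev, 1, 0.2)
  expect_identical(nrow(out), 107L)
  expect_gt(min(out$time), 1)
  expect_lte(max(out$time), 11.7 + 1e-9)
  expect_identical(nrow(trim_time(ev, 0, 0)), nrow(ev))
  expect_error(trim_time(ev, 6, 6), "empty after trim")
  expect_error(trim_time(ev[rev(seq_len(nrow(ev))), ], 1, 0.2), "time-sorted")
})

test_that("scatter gate keeps the closed FSC/SSC windows", {
  ev <- data.frame(time = 1:3 / 10,
                   fsc = c(50000, 30000, 50000),
                   ssc = c(50000, 50000, 95000), gfp = 1)
  out <- scatter_gate(ev)
  expect_identical(nrow(out), 1L)
  expect_identical(out$fsc, 50000)

  unif <- withr::with_seed(5, data.frame(
    time = sort(runif(1000, 0, 10)),
    fsc = runif(1000, 0, 150000), ssc = runif(1000, 0, 150000), gfp = 1))
  frac <- nrow(scatter_gate(unif)) / 1000
  expect_lt(abs(frac - (60 / 150) * (80 / 150)), 0.05)
})

test_that("density centre finds the modal bin with a deterministic tie-break", {
  pm <- data.frame(time = seq(0.001, 1, length.out = 150), fsc = 50000,
                   ssc = 40000, gfp = 1)
  ctr <- density_centre(pm)
  expect_lte(abs(ctr[["fsc"]] - 50000), 2500 / 2)
  expect_lte(abs(ctr[["ssc"]] - 40000), 2500 / 2)

  nrm <- withr::with_seed(9, data.frame(
    time = seq(0.001, 10, length.out = 50000),
    fsc = rnorm(50000, 60000, 8000), ssc = rnorm(50000, 30000, 8000), gfp = 1))
  ctr2 <- density_centre(nrm)
  expect_lte(abs(ctr2[["fsc"]] - 60000), 2500)
  expect_lte(abs(ctr2[["ssc"]] - 30000), 2500)

  two <- data.frame(time = seq(0.001, 1, length.out = 200),
                    fsc = rep(c(20000, 80000), each = 100),
                    ssc = rep(c(20000, 80000), each = 100), gfp = 1)
  t1 <- density_centre(two); t2 <- density_centre(two)
  expect_identical(t1, t2)                       # stable across runs
  expect_lt(t1[["fsc"]], 40000)                  # lowest-index rule
  expect_error(density_centre(pm[1:50, ]), "too few events")
})

test_that("radial gate uses the Euclidean FSC-SSC distance", {
  ctr <- c(fsc = 50000, ssc = 50000)
  ev <- data.frame(time = c(0.1, 0.2), fsc = c(53000, 50000),
                   ssc = c(54000, 50000), gfp = 1)
  expect_identical(nrow(radial_gate(ev, ctr, 5000)), 2L)   # 3-4-5 boundary kept
  expect_identical(nrow(radial_gate(ev, ctr, 4999)), 1L)
  expect_identical(nrow(radial_gate(ev, ctr, 0)), 1L)      # only the centre
  expect_identical(nrow(radial_gate(ev, ctr, 1e7)), 2L)    # radius >= max distance
})

test_that("cv is the sample SD over the mean and is scale invariant", {
  expect_equal(cv(c(10, 10, 10)), 0)
  expect_equal(cv(c(1, 2, 3)), 0.5)
  expect_equal(cv(7 * c(1, 2, 3)), cv(c(1, 2, 3)))
  expect_error(cv(c(5)), "at least 2")
  expect_error(cv(c(-2, 0)), "positive")
})

test_that("radial gating recovers the intrinsic CV from synthetic events", {
  cfg <- flow_sim_config(n_events = 50000, extrinsic_cv = 0.25,
                         intrinsic_cv = c(gfp = 0.12),
                         channel_means = c(gfp = 1000), seed = 21)
  ns <- noise_summary(simulate_events(cfg))
  expect_gt(ns$total_cv, 0.25)
  expect_lt(abs(ns$plateau_cv - 0.12) / 0.12, 0.10)

  # no extrinsic component: the curve is flat at the total CV
  cfg0 <- flow_sim_config(n_events = 20000, extrinsic_cv = 0,
                          intrinsic_cv = c(gfp = 0.12),
                          channel_means = c(gfp = 1000), seed = 22)
  ns0 <- noise_summary(simulate_events(cfg0))
  expect_lt(abs(ns0$plateau_cv - ns0$total_cv) / ns0$total_cv, 0.05)

  ev <- simulate_events(cfg0)
  ctr <- density_centre(scatter_gate(trim_time(ev)))
  expect_error(cv_vs_radius(ev, ctr, c(5000, 1000)), "radii must increase")
})

test_that("gated plateau CV approaches the intrinsic CV from above across seeds", {
  for (s in 1:3) {
    cfg <- flow_sim_config(n_events = 20000, extrinsic_cv = 0.1 * s,
                           intrinsic_cv = c(gfp = 0.10),
                           channel_means = c(gfp = 800), seed = 100 + s)
    ns <- noise_summary(simulate_events(cfg))
    expect_lt(abs(ns$plateau_cv - 0.10), abs(ns$total_cv - 0.10))
  }
})

test_that("dual-reporter estimator isolates the uncorrelated noise component", {
  expect_equal(dual_reporter_noise(c(5, 7, 9), c(5, 7, 9)), 0)
  expect_equal(dual_reporter_noise(c(2, 0), c(0, 2)), 2)

  # symmetry and invariance to common rescaling
  g <- c(3, 5, 8, 13); m <- c(4, 4, 9, 12)
  expect_equal(dual_reporter_noise(g, m), dual_reporter_noise(m, g))
  expect_equal(dual_reporter_noise(3 * g, 3 * m), dual_reporter_noise(g, m))

  cfg <- flow_sim_config(n_events = 100000, extrinsic_cv = 0.30,
                         intrinsic_cv = c(gfp = 0.10, mcherry = 0.10),
                         channel_means = c(gfp = 1000, mcherry = 400),
                         debris_frac = 0, seed = 31)
  ev <- simulate_events(cfg)
  # shared extrinsic factor drives strong inter-channel correlation
  expect_gt(cor(ev$gfp, ev$mcherry), 0.85)
  noise <- sqrt(dual_reporter_noise(ev$gfp, ev$mcherry))
  expect_lt(abs(noise - 0.10) / 0.10, 0.10)

  expect_error(dual_reporter_noise(c(1, 2), c(1, 2, 3)), "length mismatch")
})

test_that("the pipeline is a pure function of events and configuration", {
  cfg <- flow_sim_config(n_events = 20000, seed = 41)
  ev <- simulate_events(cfg)
  a <- noise_summary(ev)
  b <- noise_summary(ev)
  expect_identical(a, b)
})
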