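# Optimisers and the alternating fitting schedule.

test_that("Hooke-Jeeves solves a convex quadratic to step_min accuracy", {
  f <- function(x) sum((x - 3)^2)
  res <- hooke_jeeves(f, c(0, 0, 0), step_init = 1, step_min = 1e-4, budget = 5000)
  expect_true(all(abs(res$par - 3) <= 1e-3))
  expect_lte(res$value, f(c(0, 0, 0)))

  # zero budget returns the starting point
  res0 <- hooke_jeeves(f, c(0, 0, 0), budget = 0)
  expect_identical(res0$par, c(0, 0, 0))
})

test_that("Hooke-Jeeves beats random search on the Rosenbrock function", {
  rosen <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  budget <- 1000L
  hj <- hooke_jeeves(rosen, c(-1.2, 1), step_init = 0.5, step_min = 1e-6,
                     budget = budget)
  rnd_best <- withr::with_seed(7, {
    min(vapply(seq_len(budget), function(i)
      rosen(runif(2, -2, 2)), numeric(1)))
  })
  expect_lt(hj$value, rnd_best)
})

test_that("particle swarm finds the sphere optimum and is seed-reproducible", {
  sphere <- function(x) sum(x^2)
  res <- particle_swarm(sphere, rep(-5, 4), rep(5, 4), n_particles = 30,
                        iters = 200, seed = 11)
  expect_lt(res$value, 1e-2)
  expect_true(all(res$par >= -5 & res$par <= 5))
  res2 <- particle_swarm(sphere, rep(-5, 4), rep(5, 4), n_particles = 30,
                         iters = 200, seed = 11)
  expect_identical(res, res2)
})

test_that("objective is zero at the generating parameters and linear in weights", {
  net <- toy_network_staged(1)
  params <- cap_params(n_ligands = 1)
  totals <- cap_totals(n_ligands = 1)
  builder <- function(p) build_model(net, p, totals)
  data <- simulate_scan_dataset(builder(params), "G",
                                grid_pct = c(50, 100, 200), noise_cv = 0)
  obj <- fit_objective(params, data, builder)
  expect_lt(obj, 1e-6)

  data_off <- data
  data_off$flux_pct <- data_off$flux_pct + 5
  o1 <- fit_objective(params, data_off, builder)
  data_w <- data_off
  data_w$weight <- 2
  expect_equal(fit_objective(params, data_w, builder), 2 * o1, tolerance = 1e-8)

  expect_error(fit_objective(params, data[1:2, ], builder), "at least 3 records")
})

test_that("fit configuration enforces the 10-stage schedule and bounds", {
  init <- c(kon_G_A = -4)
  expect_error(fit_config(init, -6, -2, schedule = rep("hooke_jeeves", 9)),
               "10 stages")
  expect_error(fit_config(init, -6, -2, schedule = rep("newton", 10)),
               "unknown stage method")
  expect_error(fit_config(init, lower = -6, upper = Inf))
  cfg <- fit_config(init, -6, -2)
  expect_identical(length(cfg$schedule), 10L)
})

test_that("the alternating schedule yields a monotone, reproducible trace", {
  net <- toy_network_staged(1)
  totals <- cap_totals(n_ligands = 1)
  truth <- cap_params(n_ligands = 1)
  builder <- function(p) build_model(net, p, totals)
  data <- simulate_scan_dataset(builder(truth), "G",
                                grid_pct = c(50, 100, 200), noise_cv = 0)
  free <- c("kon_G_A", "koff_G_A")
  start <- log10(unlist(truth[free])) + c(0.5, -0.5)
  cfg <- fit_config(setNames(start, free),
                    lower = log10(unlist(truth[free])) - 2,
                    upper = log10(unlist(truth[free])) + 2,
                    hj_budget = 40L, pso_particles = 6L, pso_iters = 4L,
                    seed = 3L)
  fit <- alternating_fit(data, cfg, truth, builder)
  expect_identical(nrow(fit$trace), 10L)
  expect_true(all(diff(fit$trace$objective) <= 1e-12))
  expect_lt(fit$objective, fit_objective(replace(truth, free, 10^start),
                                         data, builder))
  fit2 <- alternating_fit(data, cfg, truth, builder)
  expect_identical(fit$par_log10, fit2$par_log10)
  expect_identical(fit$trace, fit2$trace)
})
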