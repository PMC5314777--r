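# Mass-action model construction, integration and quasi-steady state,
# validated on the 1-ligand toy network against hand-written ODEs and a
# fixed-step Runge-Kutta oracle.

toy_setup <- function() {
  net <- toy_network_staged(1)
  params <- cap_params(n_ligands = 1)
  totals <- cap_totals(n_ligands = 1)
  list(net = net, params = params, totals = totals,
       model = build_model(net, params, totals))
}

test_that("the full-size model has 213 time-dependent states and 30 parameters", {
  net <- toy_network_staged(4)
  m <- build_model(net)
  expect_identical(m$n_states, 213L)
  expect_identical(length(cap_param_names(4)), 30L)
  expect_identical(length(cap_default_params(4)), 30L)
  expect_identical(sum(m$fixed), 2L)
})

test_that("model right-hand side matches the hand-written toy ODEs", {
  ts <- toy_setup()
  p <- as.list(ts$params)
  withr::with_seed(42, {
    for (rep in 1:5) {
      x <- setNames(runif(10, 0, 5000), ts$model$labels)
      got <- capscaffold:::cap_rhs(ts$model, x)
      want <- toy_rhs(x, p)
      expect_equal(unname(got), unname(want[ts$model$labels]), tolerance = 1e-12)
    }
  })
})

test_that("with all association rates zero the free-monomer state is stationary", {
  net <- toy_network_staged(1)
  p <- cap_params(kon_G_A = 0, kon_R_A = 0, k_init = 0, n_ligands = 1)
  m <- build_model(net, p, cap_totals(n_ligands = 1))
  expect_equal(max(abs(capscaffold:::cap_rhs(m, m$x0))), 0)
})

test_that("trajectories conserve scaffold and ligand totals and match RK4", {
  ts <- toy_setup()
  tr <- simulate_timecourse(ts$model, 20)
  comp <- species_composition(ts$net)
  for (tok in c("G", "R", "A")) {
    tot <- as.matrix(tr[, -1]) %*% comp[, tok]
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
  }
  expect_true(all(as.matrix(tr[, -1]) > -1e-6))

  x_rk4 <- toy_rk4(ts$model$x0, as.list(ts$params), t_end = 2, dt = 5e-4)
  row <- simulate_timecourse(ts$model, 2)
  x_pkg <- unlist(row[nrow(row), -1])
  rel <- abs(x_pkg - x_rk4[names(x_pkg)]) / (abs(x_rk4[names(x_pkg)]) + 1e-8)
  expect_lt(max(rel), 1e-4)

  # t_end = 0 returns the initial state
  r0 <- simulate_timecourse(ts$model, 0)
  expect_equal(unlist(r0[1, -1]), ts$model$x0)
})

test_that("steady state satisfies the flux identity and conservation laws", {
  ts <- toy_setup()
  ss <- steady_state(ts$model)
  expect_true(ss$converged)
  expect_lt(ss$flux_gap, 1e-6)
  comp <- species_composition(ts$net)
  for (tok in c("G", "R", "A")) {
    expect_lt(abs(sum(ss$amounts * comp[, tok]) - ts$totals[[tok]]) / ts$totals[[tok]],
              1e-6)
  }
  expect_true(all(ss$amounts >= 0))

  # no initiation -> no translation flux
  m0 <- build_model(ts$net, cap_params(k_init = 0, n_ligands = 1), ts$totals)
  expect_equal(steady_state(m0)$flux, 0)

  # no mRNA (vanishing pool) -> no flux, no mRNA-containing complexes
  mr <- build_model(ts$net, ts$params, cap_totals(R = 1e-9, n_ligands = 1))
  ssr <- steady_state(mr)
  expect_lt(ssr$flux, 1e-9)
  r_bound <- sum(ssr$amounts[c("R.A(r)", "G.R.A(gr)", "EL")])
  expect_lt(r_bound, 1e-9)
})

test_that("abundance scans normalise at the nominal point and expose control coefficients", {
  ts <- toy_setup()
  scan <- abundance_scan(ts$model, "G", grid_pct = c(50, 80, 100, 125, 200))
  expect_equal(scan$flux_pct[scan$abundance_pct == 100], 100)
  expect_true(all(scan$converged))

  # flux proportional to abundance gives a unit control coefficient:
  # a synthetic linear scan exercises the finite-difference estimator
  lin <- scan
  lin$flux_pct <- lin$abundance_pct
  expect_equal(rate_control_coefficient(lin, 100), 1)
  flat <- scan
  flat$flux_pct <- rep(100, nrow(flat))
  expect_equal(rate_control_coefficient(flat, 100), 0)
  expect_error(rate_control_coefficient(scan, 50), "outside grid")   # boundary
  expect_error(rate_control_coefficient(scan, 90), "outside grid")   # not a grid point
})

test_that("model construction validates parameters and totals", {
  net <- toy_network_staged(1)
  p <- cap_params(n_ligands = 1)
  expect_error(build_model(net, p[-1], cap_totals(n_ligands = 1)),
               "missing rate parameter")
  expect_error(cap_totals(G = -5, n_ligands = 1), "positive")
  expect_error(build_model(generate_network(1), p), "translation stage")
})
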