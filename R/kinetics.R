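# Mass-action kinetics of the assembly network: ODE construction, stiff
# integration, quasi-steady-state refinement, abundance-response scans and
# rate-control coefficients.

#' Rate-parameter names of the assembly model
#'
#' Seven rate constants per ligand X -- `kon_G_X`/`koff_G_X` (binding to the
#' eIF4G site), `kon_R_X`/`koff_R_X` (binding to the mRNA site),
#' `kc_G_X`/`kc_R_X` (intramolecular ring closure onto eIF4G / mRNA) and
#' `koff_bridge_X` (dissociation of one bond of a doubly-bound ligand while
#' the complex stays intact) -- plus the two translation-stage constants
#' `k_init` and `k_elong`. With four ligands this is the model's full set of
#' 30 parameters (no binding cooperativity: rates are shared within a rule
#' class, not per species).
#'
#' @param n_ligands Number of ligand kinds (0-4).
#' @return Character vector of parameter names.
#' @export
cap_param_names <- function(n_ligands = 4) {
  ligs <- .cap_ligands(n_ligands)
  per <- c("kon_G", "koff_G", "kon_R", "koff_R", "kc_G", "kc_R", "koff_bridge")
  c(as.vector(t(outer(per, ligs, paste, sep = "_"))), "k_init", "k_elong")
}

#' Rate-parameter set
#'
#' Builds a named parameter vector starting from the package defaults (see
#' [cap_default_params()]); individual rates can be overridden by name.
#' Units: bimolecular association constants in (molecules/cell)^-1 s^-1, all
#' other rates in s^-1.
#'
#' @param ... Named scalar overrides, e.g. `kon_G_A = 2e-4`.
#' @param n_ligands Number of ligand kinds.
#' @return Named numeric vector of class `cap_params`.
#' @export
cap_params <- function(..., n_ligands = 4) {
  p <- cap_default_params(n_ligands)
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    p[names(ov)] <- ov
  }
  if (any(p < 0)) stop("rate parameters must be non-negative", call. = FALSE)
  structure(p, class = "cap_params", n_ligands = as.integer(n_ligands))
}

#' Default (illustrative) rate parameters
#'
#' The study this model derives from did not publish its fitted rate
#' constants, so the package ships an illustrative default set, chosen so
#' that the model exhibits the qualitative behaviour the assembly mechanism
#' implies: a unimodal (prozone) translation-flux response to eIF4G abundance
#' peaking near the physiological level, and saturating, plateau-like
#' responses to eIF4E and eIF4A. These values are NOT published estimates.
#'
#' @inheritParams cap_param_names
#' @return Named numeric vector.
#' @export
cap_default_params <- function(n_ligands = 4) {
  ligs <- .cap_ligands(n_ligands)
  p <- numeric(0)
  for (x in ligs) {
    p[paste0("kon_G_", x)] <- 2e-4
    p[paste0("koff_G_", x)] <- 2
    p[paste0("kon_R_", x)] <- 2e-4
    p[paste0("koff_R_", x)] <- 1000
    p[paste0("kc_G_", x)] <- 50
    p[paste0("kc_R_", x)] <- 50
    p[paste0("koff_bridge_", x)] <- 2
  }
  # eIF4A, the most abundant ligand, is given the weakest direct mRNA-site
  # affinity so its free-mRNA occupancy stays low even at 10x abundance
  if ("A" %in% ligs) p["koff_R_A"] <- 5000
  p["k_init"] <- 5e-5
  p["k_elong"] <- 2
  p
}

# ensure a parameter vector covers every rate reference of a network
cap_params_validate <- function(params, network) {
  need <- unique(network$reactions$rate_param)
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop("missing rate parameter(s): ", paste(missing, collapse = ", "), call. = FALSE)
  if (any(params < 0)) stop("rate parameters must be non-negative", call. = FALSE)
  params
}

#' Total molecular abundances
#'
#' Total molecules per cell for each scaffold and ligand, plus the buffered
#' (boundary) ribosome pools S43 and S40. The eIF4G default of 22 000
#' molecules per cell is the combined physiological abundance of the two
#' yeast eIF4G isomers; the other defaults are illustrative mid-log-phase
#' scale abundances.
#'
#' @param ... Named scalar overrides, e.g. `G = 44000`.
#' @param n_ligands Number of ligand kinds.
#' @return Named numeric vector of class `cap_totals`.
#' @export
cap_totals <- function(..., n_ligands = 4) {
  defaults <- c(G = 22000, R = 15000, A = 60000, E = 25000, D = 20000,
                P = 40000, S43 = 20000, S40 = 100000)
  keep <- c("G", "R", .cap_ligands(n_ligands), "S43", "S40")
  tt <- defaults[keep]
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(tt))
    if (length(bad)) stop("unknown total(s): ", paste(bad, collapse = ", "), call. = FALSE)
    tt[names(ov)] <- ov
  }
  if (any(tt <= 0)) stop("totals must be positive", call. = FALSE)
  structure(tt, class = "cap_totals", n_ligands = as.integer(n_ligands))
}

# initial state: all material in free monomers; fixed pools at their totals
initial_amounts <- function(network, totals) {
  x0 <- setNames(numeric(length(network$labels)), network$labels)
  for (m in c("G", "R", .cap_ligands(network$n_ligands)))
    x0[paste0(m, "()")] <- totals[[m]]
  if (isTRUE(network$staged)) {
    x0["S43"] <- totals[["S43"]]
    x0["S40"] <- totals[["S40"]]
  }
  x0
}

fixed_species_mask <- function(network, totals) {
  network$labels %in% c("S43", "S40") & isTRUE(network$staged)
}

#' Build the mass-action kinetic model
#'
#' Assigns each reaction its mass-action rate (rate constant times the
#' product of reactant amounts), sets the initial state with all material in
#' free monomers at the configured totals, and flags the 43S and free-40S
#' ribosome pools as fixed boundary species. For the full 4-ligand staged
#' network this gives 213 time-dependent state variables (215 species minus
#' the two fixed pools).
#'
#' @param network A staged `cap_network`.
#' @param params A [cap_params()] set covering every reaction.
#' @param totals A [cap_totals()] configuration.
#' @return An object of class `cap_model`.
#' @export
build_model <- function(network, params = cap_params(n_ligands = network$n_ligands),
                        totals = cap_totals(n_ligands = network$n_ligands)) {
  stopifnot(inherits(network, "cap_network"))
  if (!isTRUE(network$staged))
    stop("network must include the translation stage (see add_translation_stage)", call. = FALSE)
  params <- cap_params_validate(params, network)
  if (any(totals <= 0)) stop("totals must be positive", call. = FALSE)

  rx <- network$reactions
  n_sp <- length(network$labels)
  n_rx <- nrow(rx)
  pad <- n_sp + 1L  # index of the constant 1 appended to the state vector

  r1 <- vapply(rx$reactants, `[`, integer(1), 1L)
  r2 <- vapply(rx$reactants, function(r) if (length(r) > 1L) r[[2L]] else pad, integer(1))
  k <- unname(unlist(params)[rx$rate_param])

  ii <- c(unlist(rx$reactants), unlist(rx$products))
  jj <- c(rep(seq_len(n_rx), lengths(rx$reactants)),
          rep(seq_len(n_rx), lengths(rx$products)))
  xx <- c(rep(-1, sum(lengths(rx$reactants))), rep(1, sum(lengths(rx$products))))
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n_sp, n_rx))

  fixed <- fixed_species_mask(network, totals)
  structure(list(
    network = network,
    params = params,
    totals = totals,
    k = k, r1 = r1, r2 = r2, S = S,
    fixed = fixed,
    dyn = which(!fixed),
    n_states = sum(!fixed),
    x0 = initial_amounts(network, totals),
    labels = network$labels
  ), class = "cap_model")
}

#' @export
print.cap_model <- function(x, ...) {
  cat("mass-action cap-assembly model: ", length(x$labels), " species, ",
      length(x$k), " reactions, ", x$n_states, " time-dependent states\n", sep = "")
  invisible(x)
}

# full-state time derivative
cap_rhs <- function(model, x_full) {
  xp <- c(x_full, 1)
  v <- model$k * xp[model$r1] * xp[model$r2]
  dx <- as.numeric(model$S %*% v)
  dx[model$fixed] <- 0
  dx
}

# d(rate)/d(state), sparse n_rx x n_sp
cap_dvdx <- function(model, x_full) {
  xp <- c(x_full, 1)
  n_sp <- length(x_full)
  n_rx <- length(model$k)
  i <- c(seq_len(n_rx), which(model$r2 <= n_sp))
  j <- c(model$r1, model$r2[model$r2 <= n_sp])
  val <- c(model$k * xp[model$r2], (model$k * xp[model$r1])[model$r2 <= n_sp])
  Matrix::sparseMatrix(i = i, j = j, x = val, dims = c(n_rx, n_sp))
}

.cap_desolve_funcs <- function(model) {
  x_full <- model$x0
  dyn <- model$dyn
  func <- function(t, y, parms) {
    x_full[dyn] <- y
    list(cap_rhs(model, x_full)[dyn])
  }
  jac <- function(t, y, parms) {
    x_full[dyn] <- y
    J <- model$S %*% cap_dvdx(model, x_full)
    as.matrix(J[dyn, dyn])
  }
  list(func = func, jac = jac)
}

#' Integrate the model in time
#'
#' Stiff integration (lsoda, analytic Jacobian) of the dynamic species;
#' fixed pools are held constant. Conservation of the scaffold and ligand
#' totals holds along trajectories to the integration tolerance.
#'
#' @param model A `cap_model`.
#' @param t_end End time (s).
#' @param times Optional explicit output times (overrides `t_end`).
#' @param x0 Optional full initial state (defaults to the model's).
#' @param rtol,atol Integration tolerances.
#' @return Data frame of class `cap_trajectory`: `time` plus one column per
#'   species (fixed pools included as constants).
#' @export
simulate_timecourse <- function(model, t_end, times = NULL, x0 = NULL,
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "cap_model"))
  if (is.null(x0)) x0 <- model$x0
  if (is.null(times)) {
    if (t_end < 0) stop("t_end must be >= 0", call. = FALSE)
    if (t_end == 0) {
      out <- data.frame(time = 0, t(x0), check.names = FALSE)
      names(out) <- c("time", model$labels)
      class(out) <- c("cap_trajectory", "data.frame")
      return(out)
    }
    times <- seq(0, t_end, length.out = 101L)
  }
  fns <- .cap_desolve_funcs(model)
  sol <- deSolve::lsoda(y = x0[model$dyn], times = times, func = fns$func,
                        parms = NULL, jacfunc = fns$jac, jactype = "fullusr",
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("integrator failure: istate = ", attr(sol, "istate")[1], call. = FALSE)
  full <- matrix(rep(x0, each = nrow(sol)), nrow = nrow(sol),
                 dimnames = list(NULL, model$labels))
  full[, model$dyn] <- sol[, -1, drop = FALSE]
  out <- data.frame(time = sol[, 1], full, check.names = FALSE)
  names(out) <- c("time", model$labels)
  class(out) <- c("cap_trajectory", "data.frame")
  out
}

#' Quasi-steady state of the assembly model
#'
#' Integrate-then-refine: the model is integrated until the relative state
#' change falls below `rate_tol` per second, then polished by a damped
#' Newton iteration on all non-peptide species, with the six scaffold/ligand
#' conservation relations substituted for the free-monomer balance equations
#' (the mass-action Jacobian is singular along conservation laws). The
#' peptide keeps its ODE but is excluded from the residual: at quasi-steady
#' state it accumulates linearly at the translation flux
#' J = k_elong * \[EL\] = k_init * \[full complex\] * \[S43\].
#'
#' @param model A `cap_model`.
#' @param x0 Optional full starting state.
#' @param rate_tol Integration stationarity criterion (relative change / s).
#' @param newton_tol Newton residual tolerance (relative amount units).
#' @param max_newton Maximum Newton iterations.
#' @return List of class `cap_steady_state`: `amounts` (named, all species),
#'   `flux` (peptides/s/cell), `flux_gap` (relative gap between the two flux
#'   expressions), `residual`, `converged`.
#' @export
steady_state <- function(model, x0 = NULL, rate_tol = 1e-9, newton_tol = 1e-10,
                         max_newton = 100L) {
  stopifnot(inherits(model, "cap_model"))
  x <- if (is.null(x0)) model$x0 else x0
  labels <- model$labels
  pep_i <- match("PEP", labels)
  scale <- max(model$totals)
  eps <- 1e-6 * scale

  nt <- setdiff(model$dyn, pep_i)  # dynamic, non-peptide species

  rel_rate <- function(x_full) {
    dx <- cap_rhs(model, x_full)
    max(abs(dx[nt]) / (x_full[nt] + eps))
  }

  # damped Newton on non-peptide dynamic species with conservation
  # relations replacing the free-monomer equations
  comp <- species_composition(model$network)
  tokens <- c("G", "R", .cap_ligands(model$network$n_ligands))
  free_rows <- match(paste0(tokens, "()"), labels)
  cons_targets <- unlist(model$totals[tokens])
  nt_pos <- match(free_rows, nt)  # rows of the residual to replace

  residual <- function(x_full) {
    f <- cap_rhs(model, x_full)[nt]
    for (t in seq_along(tokens))
      f[nt_pos[t]] <- sum(comp[, tokens[t]] * x_full) - cons_targets[t]
    f
  }
  resid_scaled <- function(x_full, f) {
    s <- abs(f) / (x_full[nt] + eps)
    s[nt_pos] <- abs(f[nt_pos]) / cons_targets
    max(s)
  }

  newton <- function(x) {
    f <- residual(x)
    best <- resid_scaled(x, f)
    for (it in seq_len(max_newton)) {
      if (best < newton_tol) break
      J <- as.matrix((model$S %*% cap_dvdx(model, x))[nt, nt])
      for (tk in seq_along(tokens)) J[nt_pos[tk], ] <- comp[nt, tokens[tk]]
      step <- try(solve(J, -f), silent = TRUE)
      if (inherits(step, "try-error")) {
        step <- try(solve(J + diag(1e-10 * max(abs(J)), nrow(J)), -f), silent = TRUE)
        if (inherits(step, "try-error")) break
      }
      lambda <- 1
      improved <- FALSE
      for (half in 1:25) {
        x_try <- x
        x_try[nt] <- x[nt] + lambda * step
        if (min(x_try[nt]) >= -1e-9 * scale) {
          x_try[nt] <- pmax(x_try[nt], 0)
          f_try <- residual(x_try)
          r_try <- resid_scaled(x_try, f_try)
          if (r_try < best) {
            x <- x_try; f <- f_try; best <- r_try; improved <- TRUE
            break
          }
        }
        lambda <- lambda / 2
      }
      if (!improved) break
    }
    list(x = x, best = best, ok = best < newton_tol)
  }

  # phase 1: integrate until approximately stationary; once the state is
  # close (or a warm start was supplied), hand over to Newton opportunistically
  fns <- .cap_desolve_funcs(model)
  res <- NULL
  if (!is.null(x0)) {
    res <- newton(x)
    if (res$ok) x <- res$x
  }
  if (is.null(res) || !res$ok) {
    t_chunk <- 100
    for (it in 1:30) {
      rr <- rel_rate(x)
      if (rr < rate_tol) break
      if (rr < 1e-4) {
        res <- newton(x)
        if (res$ok) { x <- res$x; break }
      }
      sol <- try(deSolve::lsoda(y = x[model$dyn], times = c(0, t_chunk),
                                func = fns$func, parms = NULL,
                                jacfunc = fns$jac, jactype = "fullusr",
                                rtol = 1e-8, atol = 1e-10), silent = TRUE)
      if (inherits(sol, "try-error")) break
      x[model$dyn] <- pmax(sol[nrow(sol), -1], 0)
      t_chunk <- t_chunk * 3
    }
    if (is.null(res) || !res$ok) {
      res <- newton(x)
      x <- res$x
    }
  }
  best <- res$best
  converged <- res$ok

  el <- x[match("EL", labels)]
  full <- x[model$network$idx_full]
  s43 <- x[match("S43", labels)]
  k_elong <- unname(unlist(model$params)["k_elong"])
  k_init <- unname(unlist(model$params)["k_init"])
  flux <- unname(k_elong * el)
  flux2 <- unname(k_init * full * s43)
  structure(list(
    amounts = setNames(as.numeric(x), labels),
    flux = flux,
    flux_gap = abs(flux - flux2) / max(abs(flux), .Machine$double.xmin),
    residual = best,
    converged = isTRUE(converged)
  ), class = "cap_steady_state")
}

#' @export
print.cap_steady_state <- function(x, ...) {
  cat("quasi-steady state: flux =", signif(x$flux, 6), "peptides/s/cell;",
      "residual =", signif(x$residual, 3),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Translation flux versus factor abundance
#'
#' Re-solves the quasi-steady state over a grid of total abundances of one
#' factor (percent of its nominal total, all else unchanged) and reports the
#' flux normalised to the nominal (100%) point. The nominal point is added
#' to the grid if absent.
#'
#' @param model A `cap_model`.
#' @param kind Factor to scan: one of `"G"`, `"R"`, `"A"`, `"E"`, `"D"`,
#'   `"P"`.
#' @param grid_pct Abundance grid in percent of nominal.
#' @param warm_starts Optional list of per-grid-point starting states (e.g.
#'   the `"amounts"` attribute of a previous scan at nearby parameters); the
#'   quasi-steady-state refinement then usually succeeds without a fresh
#'   time-course.
#' @return Data frame of class `cap_scan` with columns `factor`,
#'   `abundance_pct`, `flux_pct`, `flux`, `converged`; steady-state amounts
#'   per point in `attr(, "amounts")`.
#' @export
abundance_scan <- function(model, kind,
                           grid_pct = c(10, 20, 35, 50, 65, 80, 100, 125, 150,
                                        200, 300, 500, 700, 1000),
                           warm_starts = NULL) {
  stopifnot(inherits(model, "cap_model"))
  kind <- match.arg(kind, c("G", "R", .cap_ligands(model$network$n_ligands)))
  grid_pct <- sort(unique(c(grid_pct, 100)))
  if (any(grid_pct <= 0)) stop("abundance grid must be positive", call. = FALSE)

  fluxes <- numeric(length(grid_pct))
  conv <- logical(length(grid_pct))
  amounts <- vector("list", length(grid_pct))
  warm <- NULL
  for (i in seq_along(grid_pct)) {
    m2 <- model
    m2$totals[kind] <- model$totals[[kind]] * grid_pct[i] / 100
    m2$x0 <- initial_amounts(model$network, m2$totals)
    # warm-start from the previous grid point, moving the abundance
    # difference through the scanned factor's free pool
    x_start <- NULL
    if (!is.null(warm_starts) && length(warm_starts) >= i &&
        !is.null(warm_starts[[i]])) {
      x_start <- warm_starts[[i]]
    } else if (!is.null(warm)) {
      x_start <- warm
      delta <- m2$totals[[kind]] - model$totals[[kind]] * grid_pct[i - 1] / 100
      x_start[paste0(kind, "()")] <- max(x_start[[paste0(kind, "()")]] + delta, 0)
    }
    ss <- steady_state(m2, x0 = x_start)
    fluxes[i] <- ss$flux
    conv[i] <- ss$converged
    amounts[[i]] <- ss$amounts
    if (ss$converged) warm <- ss$amounts
  }
  nominal <- fluxes[grid_pct == 100]
  out <- data.frame(factor = kind, abundance_pct = grid_pct,
                    flux_pct = 100 * fluxes / nominal,
                    flux = fluxes, converged = conv,
                    stringsAsFactors = FALSE)
  attr(out, "amounts") <- amounts
  class(out) <- c("cap_scan", "data.frame")
  out
}

#' Rate-control coefficient from a scan
#'
#' Central finite-difference slope of normalised flux versus normalised
#' abundance (both as fractions of their nominal values) at a grid point of
#' an abundance scan: the scaled sensitivity of pathway flux to the factor's
#' abundance. A flux proportional to abundance gives 1, a flat response 0.
#'
#' @param scan A `cap_scan`.
#' @param at_percent Interior grid point (percent of nominal).
#' @return Numeric scalar.
#' @export
rate_control_coefficient <- function(scan, at_percent = 100) {
  stopifnot(inherits(scan, "cap_scan"))
  x <- scan$abundance_pct
  i <- which(abs(x - at_percent) < 1e-8)
  if (length(i) != 1L || i == 1L || i == length(x))
    stop("point outside grid: `at_percent` must be an interior grid point", call. = FALSE)
  (scan$flux_pct[i + 1L] - scan$flux_pct[i - 1L]) / (x[i + 1L] - x[i - 1L])
}

#' Scaffold sequestration diagnostic
#'
#' Summed steady-state amount of eIF4G-containing complexes that lack mRNA
#' (at least one ligand bound to G, no R). Growth of this pool under excess
#' eIF4G is the model's explanation of the prozone inhibition: surplus
#' scaffold distorts the distribution of partners across incomplete
#' intermediates.
#'
#' @param network A `cap_network`.
#' @param amounts Named species amounts (e.g. from [steady_state()]).
#' @return Numeric scalar.
#' @export
scaffold_sequestration <- function(network, amounts) {
  stopifnot(inherits(network, "cap_network"))
  sel <- vapply(network$species, function(sp) {
    !inherits(sp, "cap_stage_species") && sp$g && !sp$r && length(sp$lig) > 0L
  }, logical(1))
  sum(amounts[network$labels[sel]])
}
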