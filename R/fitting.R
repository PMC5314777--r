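# Rate-parameter estimation from abundance-rate data: weighted least squares
# on normalised flux curves, minimised by a 10-stage schedule alternating
# Hooke-Jeeves pattern search with global-best particle-swarm optimisation.
# All searching is done in log10 parameter space, the natural scale for rate
# constants spanning decades.

#' Weighted objective for abundance-rate data
#'
#' Weighted sum of squared differences between the model's normalised flux
#' (percent of nominal, via [abundance_scan()] at the dataset's abundances)
#' and the observed `flux_pct`. Grid points whose steady state fails to
#' converge contribute a large finite penalty instead of an error, so a
#' search can traverse and escape pathological parameter regions.
#'
#' @param params A named rate-parameter vector accepted by `model_builder`.
#' @param dataset Data frame with columns `factor`, `abundance_pct`,
#'   `flux_pct`, `weight` (at least 3 records).
#' @param model_builder Function mapping a parameter vector to a
#'   `cap_model`.
#' @param penalty Objective contribution per non-converged point.
#' @param cache Optional environment carrying steady-state warm starts
#'   between objective calls at nearby parameters (used by
#'   [alternating_fit()] to avoid re-integrating from scratch).
#' @return Numeric scalar (units: squared flux percent).
#' @export
fit_objective <- function(params, dataset, model_builder, penalty = 1e6,
                          cache = NULL) {
  dataset <- validate_fit_dataset(dataset)
  model <- model_builder(params)
  total <- 0
  for (kind in unique(dataset$factor)) {
    d <- dataset[dataset$factor == kind, ]
    grid <- sort(unique(c(d$abundance_pct, 100)))
    warm <- if (!is.null(cache)) cache[[kind]] else NULL
    scan <- try(abundance_scan(model, kind, grid_pct = grid,
                               warm_starts = warm), silent = TRUE)
    if (inherits(scan, "try-error")) return(penalty * nrow(d))
    if (!is.null(cache) && all(scan$converged)) cache[[kind]] <- attr(scan, "amounts")
    ok <- scan$converged[match(d$abundance_pct, scan$abundance_pct)]
    pred <- scan$flux_pct[match(d$abundance_pct, scan$abundance_pct)]
    total <- total + sum(ifelse(ok, d$weight * (pred - d$flux_pct)^2, penalty))
  }
  total
}

validate_fit_dataset <- function(dataset) {
  need <- c("factor", "abundance_pct", "flux_pct")
  if (!all(need %in% names(dataset)))
    stop("dataset needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (is.null(dataset$weight)) dataset$weight <- 1
  if (nrow(dataset) < 3L) stop("at least 3 records required", call. = FALSE)
  if (any(dataset$abundance_pct <= 0)) stop("abundance_pct must be positive", call. = FALSE)
  dataset
}

#' Hooke-Jeeves pattern search
#'
#' Classic derivative-free minimisation: coordinate-wise exploratory moves
#' of size `step`, followed by pattern (extrapolation) moves along the
#' accepted direction; the step is halved whenever exploration fails, and
#' the search stops at `step_min` or when the evaluation budget is spent.
#' The returned value is never worse than `f(x0)`.
#'
#' @param f Objective function of a numeric vector.
#' @param x0 Starting point.
#' @param step_init,step_min Initial and terminal step sizes
#'   (`step_init > step_min > 0`).
#' @param budget Maximum number of function evaluations.
#' @return List with `par`, `value`, `evals`.
#' @export
hooke_jeeves <- function(f, x0, step_init = 0.5, step_min = 1e-3, budget = 500L) {
  stopifnot(step_init > step_min, step_min > 0)
  evals <- 0L
  fe <- function(x) { evals <<- evals + 1L; f(x) }
  if (budget <= 0L) return(list(par = x0, value = f(x0), evals = 1L))

  explore <- function(x, fx, step) {
    for (i in seq_along(x)) {
      for (s in c(step, -step)) {
        if (evals >= budget) break
        xt <- x; xt[i] <- xt[i] + s
        ft <- fe(xt)
        if (ft < fx) { x <- xt; fx <- ft; break }
      }
    }
    list(x = x, fx = fx)
  }

  base <- x0; f_base <- fe(base)
  step <- step_init
  while (step >= step_min && evals < budget) {
    ex <- explore(base, f_base, step)
    if (ex$fx < f_base) {
      repeat {  # pattern moves while they keep paying off
        pattern <- ex$x + (ex$x - base)
        base <- ex$x; f_base <- ex$fx
        if (evals >= budget) break
        f_pat <- fe(pattern)
        ex2 <- explore(pattern, f_pat, step)
        if (ex2$fx < f_base) ex <- ex2 else break
      }
    } else {
      step <- step / 2
    }
  }
  list(par = base, value = f_base, evals = evals)
}

#' Global-best particle-swarm optimisation
#'
#' Standard PSO with inertia and cognitive/social coefficients (defaults
#' 0.7, 1.5, 1.5), positions clamped to the box bounds. Fully reproducible
#' for a given seed; an optional `init` point is injected as the first
#' particle so a swarm stage can warm-start from an incumbent.
#'
#' @param f Objective function.
#' @param lower,upper Box bounds (finite numeric vectors).
#' @param n_particles Swarm size (>= 2).
#' @param iters Number of iterations.
#' @param seed RNG seed.
#' @param w,c1,c2 Inertia, cognitive and social coefficients.
#' @param init Optional starting point for the first particle.
#' @return List with `par`, `value`, `evals`.
#' @export
particle_swarm <- function(f, lower, upper, n_particles = 20L, iters = 50L,
                           seed = 1L, w = 0.7, c1 = 1.5, c2 = 1.5, init = NULL) {
  stopifnot(n_particles >= 2L, all(is.finite(lower)), all(is.finite(upper)),
            all(upper > lower))
  d <- length(lower)
  withr::with_seed(seed, {
    pos <- matrix(runif(n_particles * d, lower, upper), nrow = n_particles,
                  byrow = TRUE)
    if (!is.null(init)) pos[1, ] <- pmin(pmax(init, lower), upper)
    vmax <- (upper - lower) / 4
    vel <- matrix(runif(n_particles * d, -vmax, vmax), nrow = n_particles,
                  byrow = TRUE)
    pbest <- pos
    pval <- apply(pos, 1, f)
    g <- which.min(pval)
    gbest <- pbest[g, ]; gval <- pval[g]
    evals <- n_particles
    for (it in seq_len(iters)) {
      r1 <- matrix(runif(n_particles * d), nrow = n_particles)
      r2 <- matrix(runif(n_particles * d), nrow = n_particles)
      vel <- w * vel + c1 * r1 * (pbest - pos) +
        c2 * r2 * (matrix(gbest, n_particles, d, byrow = TRUE) - pos)
      vel <- pmin(pmax(vel, matrix(-vmax, n_particles, d, byrow = TRUE)),
                  matrix(vmax, n_particles, d, byrow = TRUE))
      pos <- pos + vel
      pos <- pmin(pmax(pos, matrix(lower, n_particles, d, byrow = TRUE)),
                  matrix(upper, n_particles, d, byrow = TRUE))
      fv <- apply(pos, 1, f)
      evals <- evals + n_particles
      upd <- fv < pval
      pbest[upd, ] <- pos[upd, , drop = FALSE]
      pval[upd] <- fv[upd]
      g <- which.min(pval)
      if (pval[g] < gval) { gbest <- pbest[g, ]; gval <- pval[g] }
    }
    list(par = gbest, value = gval, evals = evals)
  })
}

#' Configuration for the alternating fit
#'
#' Ten optimisation stages alternating Hooke-Jeeves pattern search with
#' particle-swarm optimisation, each warm-started from the incumbent best
#' point. Parameters are searched on the log10 scale within finite box
#' bounds.
#'
#' @param par_init Named log10 starting values of the free parameters.
#' @param lower,upper Log10 box bounds (same names/length as `par_init`).
#' @param schedule Character vector of stage methods; must have length 10
#'   and contain only `"hooke_jeeves"` / `"particle_swarm"`.
#' @param hj_budget Evaluation budget per Hooke-Jeeves stage.
#' @param hj_step_init,hj_step_min Hooke-Jeeves step sizes (log10 units).
#' @param pso_particles,pso_iters Swarm size and iterations per PSO stage.
#' @param seed Base RNG seed (per-stage seeds are derived from it).
#' @return List of class `cap_fit_config`.
#' @export
fit_config <- function(par_init, lower, upper,
                       schedule = rep(c("hooke_jeeves", "particle_swarm"), 5),
                       hj_budget = 200L, hj_step_init = 0.25, hj_step_min = 1e-4,
                       pso_particles = 12L, pso_iters = 12L, seed = 1L) {
  if (length(schedule) != 10L)
    stop("schedule must have exactly 10 stages", call. = FALSE)
  if (!all(schedule %in% c("hooke_jeeves", "particle_swarm")))
    stop("unknown stage method in schedule", call. = FALSE)
  stopifnot(length(lower) == length(par_init), length(upper) == length(par_init),
            all(is.finite(lower)), all(is.finite(upper)), all(upper > lower),
            all(par_init >= lower), all(par_init <= upper))
  structure(list(par_init = par_init, lower = lower, upper = upper,
                 schedule = schedule, hj_budget = as.integer(hj_budget),
                 hj_step_init = hj_step_init, hj_step_min = hj_step_min,
                 pso_particles = as.integer(pso_particles),
                 pso_iters = as.integer(pso_iters), seed = as.integer(seed)),
            class = "cap_fit_config")
}

#' Alternating Hooke-Jeeves / particle-swarm fit
#'
#' Runs the 10-stage schedule of `config` against [fit_objective()] for the
#' given dataset. The free parameters named in `config$par_init` are varied
#' on the log10 scale; all other rates are taken from `base_params`. Each
#' stage is warm-started from the incumbent, so the best objective is
#' non-increasing across stages and the whole trace is reproducible from
#' the seed.
#'
#' @param dataset A fit dataset (see [fit_objective()]).
#' @param config A [fit_config()].
#' @param base_params Full named rate-parameter vector holding the fixed
#'   rates.
#' @param model_builder Function mapping a full parameter vector to a
#'   `cap_model`.
#' @return List of class `cap_fit`: `par_log10`, `params` (full, natural
#'   scale), `objective`, per-stage `trace`, `evaluations`.
#' @export
alternating_fit <- function(dataset, config, base_params, model_builder) {
  stopifnot(inherits(config, "cap_fit_config"))
  dataset <- validate_fit_dataset(dataset)
  free <- names(config$par_init)
  if (is.null(free) || !all(free %in% names(base_params)))
    stop("config$par_init must be named with parameters of base_params", call. = FALSE)

  cache <- new.env(parent = emptyenv())
  fwrap <- function(theta) {
    p <- base_params
    p[free] <- 10^theta
    fit_objective(p, dataset, model_builder, cache = cache)
  }

  incumbent <- config$par_init
  best <- fwrap(incumbent)
  evals <- 1L
  trace <- data.frame(stage = integer(0), method = character(0),
                      objective = numeric(0), evals = integer(0))
  for (s in seq_along(config$schedule)) {
    method <- config$schedule[[s]]
    res <- if (method == "hooke_jeeves") {
      hooke_jeeves(fwrap, incumbent, step_init = config$hj_step_init,
                   step_min = config$hj_step_min, budget = config$hj_budget)
    } else {
      particle_swarm(fwrap, config$lower, config$upper,
                     n_particles = config$pso_particles,
                     iters = config$pso_iters, seed = config$seed + s,
                     init = incumbent)
    }
    if (res$value < best) {
      incumbent <- setNames(pmin(pmax(res$par, config$lower), config$upper), free)
      best <- res$value
    }
    evals <- evals + res$evals
    trace <- rbind(trace, data.frame(stage = s, method = method,
                                     objective = best, evals = res$evals))
  }
  p_final <- base_params
  p_final[free] <- 10^incumbent
  structure(list(par_log10 = incumbent, params = p_final, objective = best,
                 trace = trace, evaluations = evals), class = "cap_fit")
}

#' @export
print.cap_fit <- function(x, ...) {
  cat("alternating Hooke-Jeeves / particle-swarm fit\n")
  cat("  final objective:", signif(x$objective, 6), "after", x$evaluations,
      "evaluations\n")
  print(x$trace, row.names = FALSE)
  invisible(x)
}
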