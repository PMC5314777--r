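# Synthetic-data generators: cytometry events with controlled
# intrinsic/extrinsic noise structure, overdispersed per-cell mRNA counts,
# noisy abundance-rate datasets sampled from the kinetic model, and
# competition colony counts. Every generator is a deterministic function of
# (config, seed).

# mean-1 log-normal deviates with a given CV
.rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Flow-cytometry simulation configuration
#'
#' Each simulated cell carries a shared extrinsic scale factor s (mean-1
#' log-normal with CV `extrinsic_cv`) standing for cell size / cycle stage:
#' every fluorescence channel is `mean * s * (1 + e)` with an independent
#' intrinsic normal deviate e of CV `intrinsic_cv`, and FSC/SSC scale with
#' `s^scatter_coupling` plus their own measurement noise. A `debris_frac`
#' fraction of events is replaced by small-scatter debris falling below the
#' default FSC window. Timestamps are uniform over the acquisition.
#'
#' @param n_events Number of events.
#' @param duration Acquisition duration (s).
#' @param extrinsic_cv Shared (cell-size) CV.
#' @param intrinsic_cv Named per-channel intrinsic CVs, e.g.
#'   `c(gfp = 0.1, mcherry = 0.1)`.
#' @param channel_means Named per-channel mean intensities (a.u.).
#' @param fsc_mean,fsc_cv,ssc_mean,ssc_cv Scatter means and measurement
#'   CVs.
#' @param scatter_coupling Exponent linking scatter to the extrinsic
#'   factor.
#' @param debris_frac Fraction of debris events in [0, 1).
#' @param seed RNG seed.
#' @return List of class `cap_flow_sim_config`.
#' @export
flow_sim_config <- function(n_events = 50000L, duration = 60,
                            extrinsic_cv = 0.25,
                            intrinsic_cv = c(gfp = 0.10),
                            channel_means = c(gfp = 1000),
                            fsc_mean = 70000, fsc_cv = 0.03,
                            ssc_mean = 50000, ssc_cv = 0.03,
                            scatter_coupling = 1, debris_frac = 0.02,
                            seed = 1L) {
  stopifnot(n_events >= 1L, duration > 0, extrinsic_cv >= 0,
            all(intrinsic_cv >= 0), all(channel_means > 0),
            fsc_mean > 0, ssc_mean > 0, fsc_cv >= 0, ssc_cv >= 0,
            debris_frac >= 0, debris_frac < 1)
  if (!identical(sort(names(intrinsic_cv)), sort(names(channel_means))))
    stop("intrinsic_cv and channel_means must name the same channels", call. = FALSE)
  structure(as.list(environment()), class = "cap_flow_sim_config")
}

#' Simulate a flow-cytometry event table
#'
#' @param config A [flow_sim_config()].
#' @return Event table (data frame): `time`, `fsc`, `ssc`, one column per
#'   configured channel; time-sorted.
#' @export
simulate_events <- function(config) {
  stopifnot(inherits(config, "cap_flow_sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_events
    s <- .rlnorm_cv(n, config$extrinsic_cv)
    out <- data.frame(time = sort(runif(n, 0, config$duration)))
    sc <- s^config$scatter_coupling
    out$fsc <- pmax(config$fsc_mean * sc * (1 + rnorm(n, 0, config$fsc_cv)), 0)
    out$ssc <- pmax(config$ssc_mean * sc * (1 + rnorm(n, 0, config$ssc_cv)), 0)
    for (ch in names(config$channel_means)) {
      out[[ch]] <- pmax(config$channel_means[[ch]] * s *
                          (1 + rnorm(n, 0, config$intrinsic_cv[[ch]])), 0)
    }
    n_deb <- round(config$debris_frac * n)
    if (n_deb > 0) {
      idx <- sample.int(n, n_deb)
      out$fsc[idx] <- runif(n_deb, 1000, 35000)  # below the FSC debris gate
      out$ssc[idx] <- runif(n_deb, 500, 8000)
    }
    out
  })
}

#' Simulate per-cell mRNA counts
#'
#' Negative-binomial counts parameterised by target mean and CV
#' (`size = 1/(cv^2 - 1/mean)`); when the target dispersion sits at the
#' Poisson floor (`cv^2 = 1/mean`) Poisson counts are drawn instead.
#' Sub-Poisson targets (`cv^2 < 1/mean`) are infeasible for counts and
#' rejected.
#'
#' @param mean Target mean copies per cell (> 0).
#' @param cv Target coefficient of variation.
#' @param n Number of cells.
#' @param seed RNG seed.
#' @param gene Optional gene label (attached as an attribute).
#' @return Integer vector of per-cell counts.
#' @export
simulate_mrna_counts <- function(mean, cv, n, seed = 1L, gene = NULL) {
  stopifnot(mean > 0, n >= 2L)
  excess <- cv^2 - 1 / mean
  if (excess < -1e-9)
    stop("sub-Poisson dispersion (cv^2 < 1/mean) is infeasible for counts",
         call. = FALSE)
  counts <- withr::with_seed(seed, {
    if (excess <= 1e-9) rpois(n, mean)
    else rnbinom(n, mu = mean, size = 1 / excess)
  })
  structure(as.integer(counts), gene = gene)
}

#' Simulate a noisy abundance-rate dataset
#'
#' Steady-state fluxes of a generating model at the grid abundances, each
#' replicate multiplied by mean-1 log-normal noise of the stated CV: the
#' input expected by [alternating_fit()].
#'
#' @param model Generating `cap_model`.
#' @param kind Scanned factor.
#' @param grid_pct Abundance grid (percent of nominal).
#' @param noise_cv Multiplicative noise CV (0 = exactly on the model
#'   curve).
#' @param replicates Independent replicates per grid point.
#' @param seed RNG seed.
#' @param weight Weight attached to every record.
#' @return Fit dataset data frame: `factor`, `abundance_pct`, `flux_pct`,
#'   `weight`.
#' @export
simulate_scan_dataset <- function(model, kind, grid_pct, noise_cv = 0,
                                  replicates = 1L, seed = 1L, weight = 1) {
  stopifnot(noise_cv >= 0, replicates >= 1L)
  scan <- abundance_scan(model, kind, grid_pct = grid_pct)
  scan <- scan[scan$abundance_pct %in% grid_pct, ]
  if (!all(scan$converged)) stop("generating model failed to converge", call. = FALSE)
  base <- scan$flux_pct
  withr::with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
      data.frame(factor = kind, abundance_pct = scan$abundance_pct,
                 flux_pct = base * .rlnorm_cv(length(base), noise_cv),
                 weight = weight, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Simulate a growth-competition colony-count quadruple
#'
#' Binomial plating of a 1:1 starting mixture and of the end-point mixture
#' implied by the overall fitness ratio of the tested strain across the
#' assay (expected tested fraction r / (1 + r)), so that
#' [competition_fraction()] applied to the output is unbiased within
#' binomial error.
#'
#' @param true_fitness_ratio Overall tested:competitor growth ratio across
#'   the assay (> 0).
#' @param n_colonies Colonies counted per time point (> 0).
#' @param seed RNG seed.
#' @return List of class `cap_competition_counts` with `tested_t0`,
#'   `tested_t98`, `competitor_t0`, `competitor_t98`.
#' @export
simulate_competition <- function(true_fitness_ratio, n_colonies, seed = 1L) {
  if (!is.numeric(true_fitness_ratio) || true_fitness_ratio <= 0)
    stop("true_fitness_ratio must be positive", call. = FALSE)
  if (!is.numeric(n_colonies) || n_colonies < 2)
    stop("n_colonies must be at least 2", call. = FALSE)
  withr::with_seed(seed, {
    p_end <- true_fitness_ratio / (1 + true_fitness_ratio)
    t0_tested <- rbinom(1, n_colonies, 0.5)
    t98_tested <- rbinom(1, n_colonies, p_end)
    # a zero plate count would make the ratio undefined; redraw-free clamp
    t0_tested <- min(max(t0_tested, 1L), n_colonies - 1L)
    t98_tested <- min(max(t98_tested, 1L), n_colonies - 1L)
    structure(list(tested_t0 = t0_tested,
                   tested_t98 = t98_tested,
                   competitor_t0 = n_colonies - t0_tested,
                   competitor_t98 = n_colonies - t98_tested),
              class = "cap_competition_counts")
  })
}
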