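---
title: "Methods: combinatorial cap-complex assembly, rate control and expression noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorial cap-complex assembly, rate control and expression noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capscaffold)
```

## The scientific problem

Translation initiation in budding yeast is organised around the cap-binding
(eIF4F) complex: the scaffold protein eIF4G binds the cap-binding protein
eIF4E, the DEAD-box helicase eIF4A, the helicase Ded1 and the poly(A)-binding
protein Pab1, and assembles them on the mRNA, which acts as a second
scaffold. Because eIF4G is a multivalent scaffold present at comparatively low
abundance (~22 000 molecules per cell for both isomers combined), its
abundance is predicted to control the rate of translation non-monotonically:
too little eIF4G starves assembly, while an excess titrates the partners into
incomplete, mRNA-free intermediates (the prozone, or hook, effect). The same
mechanistic position makes the cell-to-cell variability (noise) of eIF4G
expression consequential. This package implements both halves of that
analysis: the mechanistic assembly/flux model, and the single-cell statistics
used to measure expression noise.

## The assembly network

### Rule grammar

Two scaffolds (G = eIF4G, R = mRNA) and four bivalent ligands (A = eIF4A,
E = eIF4E, D = Ded1, P = Pab1). Each ligand has one G-facing and one R-facing
site; each scaffold has one dedicated site per ligand. Complexes obey two
structural constraints:

* at most one copy of each molecule per complex, and
* no direct G–R bond (the scaffolds are only connected through bridging
  ligands).

These are the unique simple constraints under which the rule expansion yields
the characteristic network sizes of this assembly scheme — 211 species and
872 reversible binding reactions (1744 irreversible) at four ligands — so the
package adopts them as pinned-by-counts. A species is therefore fully
described by which scaffolds it contains and, for each ligand present, its
bond state: bound to G only (`g`), to R only (`r`), or bridging both (`gr`).
Connectivity requires every G&R complex to contain at least one bridging
ligand. Closed forms follow for any ligand count *n*: the species count is
*n* + 2^(n+1) + 4^n − 3^n and the reversible-pair count
*n*(2^n + 4^n − 2·3^(n−1)); the test suite checks both against an
independent brute-force graph-growing oracle for *n* = 0–3.

Four forward rule classes generate the reactions: free-ligand binding to a
G-containing complex (180 reactions at *n* = 4), free-ligand binding to an
R-containing complex (180), bimolecular bridging of a G-only and an R-only
complex with disjoint ligand content (216; disjointness is forced by the
single-copy rule), and intramolecular ring closure of a singly tethered
ligand (296). Every forward binding has exactly one reverse (terminal
unbinding, fission of a sole bridge, or in-ring bond opening).

### Translation stage

Two irreversible reactions convert the assembly pathway into a flux-carrying
cycle: the fully assembled complex (all four ligands bridging both
scaffolds — chosen as the unique doubly-linked species so that exactly two
reactions close the cycle) binds the 43S preinitiation complex, producing an
elongating ribosome and releasing the free proteins; the elongating ribosome
then resolves into a free 40S subunit, a peptide and free mRNA. This adds
four species (S43, EL, S40, PEP) for 215 species and 1746 reactions in the
final model.

## Mass-action kinetics

Amounts are molecules per cell; bimolecular rate constants are in
(molecules/cell)⁻¹·s⁻¹ and all other rates in s⁻¹ (no volume conversion).
S43 and free 40S are buffered boundary pools, fixed at their configured
amounts, leaving 213 time-dependent states. The peptide keeps its ODE but is
excluded from stationarity: at quasi-steady state it accumulates linearly at
the translation flux J = k_elong·[EL] = k_init·[full]·[S43], and the
relative gap between the two expressions (≤ 1e−6 at convergence) is the
model's internal consistency check.

No binding cooperativity is assumed: rates are shared per rule class and
ligand, giving 7 parameters per ligand (association/dissociation per
scaffold site, two ring-closure rates, one in-ring dissociation rate) plus
the two stage constants — 30 in all.

### Steady-state solver

`steady_state()` integrates the stiff system (lsoda, analytic sparse
Jacobian, rtol 1e−8 / atol 1e−10) until the relative state change falls
below 1e−9 s⁻¹, then polishes with a damped Newton iteration to a residual
of 1e−10 in relative amount units. Because mass-action Jacobians are
singular along conservation laws, the six scaffold/ligand conservation
relations replace the free-monomer balance rows in the Newton system. Two
accelerations do not change the converged result: once the integrated state
is within 1e−4 s⁻¹ of stationarity Newton is attempted early, and scans
warm-start each grid point from the previous solution (moving the abundance
increment through the scanned factor's free pool). Steps that would drive
any amount below zero are damped; non-convergence is flagged, never fatal.

### Default parameters and totals

The fitted rate constants behind this model were never published, so the
package ships an illustrative default set, selected once so that the model
expresses the qualitative behaviour the mechanism implies, and clearly
labelled non-published. Association rates are 2e−4 (molecules/cell)⁻¹s⁻¹
(diffusion-limited scale for a yeast cell volume). Ligand sites on eIF4G are
strong (koff 2 s⁻¹, Kd ≈ 10⁴ molecules), direct ligand–mRNA sites weak
(koff 1000 s⁻¹; 5000 s⁻¹ for the abundant eIF4A), and ring closure fast
(50 s⁻¹ against 2 s⁻¹ in-ring opening), reflecting the high local
concentration of a tethered ligand. The weak mRNA-side affinities matter
qualitatively: if free mRNA carried ligands at high occupancy, a surplus of
any ligand would block bimolecular bridging through the disjoint-content
rule and produce a spurious ligand prozone; with weak direct binding the
eIF4E and eIF4A responses saturate into the expected plateau instead.
Totals are 22 000 eIF4G, 15 000 mRNA, 60 000 eIF4A, 25 000 eIF4E,
20 000 Ded1, 40 000 Pab1, with 20 000 S43 and 100 000 40S buffered
(mid-log-phase scale). Under these defaults the eIF4G scan is unimodal with
its maximum at the nominal abundance, flux falls on both flanks (47% of
nominal at 20% abundance, 13% at 500%), and the mRNA-free eIF4G-complex
pool grows about four-fold between 100% and 500% abundance — the
sequestration signature of the prozone.

### Scans and rate control

`abundance_scan()` re-solves the steady state over a grid of one factor's
total abundance (percent of nominal, all else fixed) and normalises flux to
the nominal point. `rate_control_coefficient()` is the central
finite-difference slope of normalised flux versus normalised abundance — a
scaled flux-control sensitivity: 1 for proportional response, 0 on a
plateau or at the interior maximum.

## Parameter fitting

`alternating_fit()` minimises a weighted sum of squared differences between
model and observed normalised flux over a 10-stage schedule alternating
Hooke-Jeeves pattern search with global-best particle-swarm optimisation,
each stage warm-started from the incumbent (so the best objective is
non-increasing and the whole trace is reproducible from the seed). Search is
in log10 parameter space, the natural scale for rate constants spanning
decades. Stage hyperparameters (HJ budget 200 evaluations, initial step
0.2 dex, terminal step 1e−6; PSO 8 particles × 6 iterations, inertia 0.7,
cognitive/social 1.5) are package defaults, all overridable. Steady-state
failures contribute a finite penalty (1e6) rather than an error so the
search can escape pathological regions.

The packaged recovery experiment (analysis step 3) runs on the 2-ligand
reduced network (21 species after staging) rather than the full model —
the reduced model is solved two orders of magnitude faster at identical
code paths, and curve-level recovery, not network scale, is what the
experiment probes. Two representative rate constants are freed and
perturbed by ±0.5 dex: on noiseless data the schedule recovers the
generating curve to machine-level objective values; under 5% multiplicative
noise the recovered curve stays within a few percent RMS of the generator.
With more simultaneous free parameters the objective valley becomes
strongly degenerate and individual rate constants are no longer
identifiable; recovery claims are therefore stated at curve level only.

## Expression-noise pipeline

The gating pipeline is a pure function of (events, configuration): trim the
first 1 s and last 0.2 s of acquisition; keep FSC in 40 000–100 000 and SSC
in 10 000–90 000 (closed windows); locate the highest-density centre of the
FSC–SSC scatterplot; and compute the channel CV inside discs of increasing
radius around it. Specific choices the method leaves open are fixed as
follows:

* **CV estimator** — sample (n−1) standard deviation over the mean,
  everywhere (shared by the smFISH count summaries).
* **Density centre** — modal bin of a 2-D histogram with 2 500 a.u. bins;
  ties broken by the larger 3×3 smoothed neighbourhood mass, then lowest
  bin indices, making the centre deterministic.
* **Plateau rule** — the CV-versus-radius curve approaches a minimum as the
  gate tightens; the plateau estimate is the mean over the 3 smallest radii
  retaining ≥ 200 events, with a warning if their relative spread exceeds
  10%.
* **Dual-reporter normalisation** — the estimator
  Noise² = ⟨(GFP − mCherry)²⟩ / (2⟨GFP⟩⟨mCherry⟩) is applied after scaling
  both channels to a common mean (the two fusions differ in absolute
  brightness); the option is switchable. The factor 2 in the denominator
  makes √Noise² an estimate of the per-channel uncorrelated (intrinsic)
  CV; with a shared extrinsic factor of CV c the estimate carries a
  √(1 + c²) inflation (≈ 4% at c = 0.3), which is inside the pipeline's
  stated 10% recovery tolerance.
* **Total CV** — reported on time-trimmed events before scatter-based
  gating, so the scatter and radial gates can only remove variance from it.

## Synthetic data

The generators provide every input the pipelines need. Cytometry events use
a minimal intrinsic/extrinsic structure: a mean-1 log-normal extrinsic
factor per cell shared by all channels, independent normal intrinsic
deviates per channel (clipped at zero), FSC/SSC proportional to the
extrinsic factor with small (CV 0.03) measurement noise, uniform
timestamps, and a debris fraction placed below the FSC window. mRNA counts
are negative-binomial in a mean/CV parameterisation (Poisson at the
dispersion floor; sub-Poisson targets are rejected as infeasible).
Competition platings are binomial draws at the start (1:1) and end
(r/(1+r)) fractions. Every generator is a deterministic function of its
configuration and seed.

What the generators do *not* emulate — instrument artefacts beyond debris
(carry-over, saturation, spectral overlap), cell-cycle substructure,
non-log-normal size distributions, correlated transcription bursting across
genes — bounds what passing tests show: the pipelines provably recover the
generating structure of this idealised model, which is a necessary, not
sufficient, condition for accuracy on instrument data.

## Problem sizes and runtime choices

The analysis workflow uses the full 215-species model for steady states and
abundance scans (a full scan solves ~14 steady states in a few seconds),
the 2-ligand reduced model for the fitting experiments, 50 000 events for
radial-gating recovery, 100 000 events for the dual-reporter estimator,
100 000 cells for count statistics and 10 000 colonies per competition
plating — sizes at which the stochastic recovery tolerances (10% relative)
sit comfortably above Monte-Carlo error.

## Known limitations

* The shipped rate constants are illustrative; quantitative flux curves are
  not predictions, only the qualitative prozone/plateau structure is.
* The choice of the all-bridged species as the 43S substrate, and of
  S43/S40 as the buffered pools, are reconstruction decisions consistent
  with the 213-ODE state count; other all-six-component species could in
  principle serve as the substrate.
* Rate constants are not constrained to thermodynamic (detailed-balance)
  consistency across binding cycles.
* The grammar is not a general rule language: no multi-copy complexes,
  polymers, or user-defined molecule types; no stochastic simulation.
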