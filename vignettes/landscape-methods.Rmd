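---
title: "Methods: stochastic landscapes of the cancer-EMT-stemness circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic landscapes of the cancer-EMT-stemness circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its model and of every design
decision a maintainer would want to audit. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The model

Six species — P53, MDM2, ZEB, OCT4, miR-145, miR-200 — interact through 16
regulations (7 activations, 9 repressions). Each regulation is one binding
site on the target gene's promoter. The reaction set is:

* **synthesis** of species $i$ at rate $g_0 \prod_r \lambda_r$ over its
  bound sites, with $\lambda_a = 8$ (activator bound) and $\lambda_r = 0.5$
  (repressor bound); a gene with $n$ sites realizes $2^n$ synthesis rates;
* **degradation** of free copies at $k\,n$ with $k = 1$;
* **binding** of an $m$-mer of the source species with propensity
  $h\,n$ ($m=1$), $h\,n(n-1)/2$ ($m=2$) or $h\,n(n-1)(n-2)(n-3)/6$
  ($m=4$; the printed divisor 6 is used verbatim), sequestering $m$ copies;
* **unbinding** at $f = k\,\omega$, releasing the $m$ copies.

The adiabatic parameter $\omega = f/k$ is 1000 by default: binding
equilibrates three orders of magnitude faster than protein turnover. The
joint process is a Markov jump process whose master equation
$\partial P/\partial t = (M_0 + M_b)P$ we solve by exact Gillespie
simulation (compiled inner loop with incremental propensity updates; on the
default network roughly $10^7$ events/s, 3.5 × 10^4 events per time unit).
Sequestered (gene-bound) copies do not degrade; degradation acts on free
copies only. The default initial condition is all-zero copy numbers with
all sites unbound; the pipeline overrides this (Section 4).

The potential landscape is $U = -\ln P$ over the (P53, ZEB, OCT4) marginal,
estimated from exact dwell-time (time-weighted) occupancy accumulated
during simulation — not from thinned records, whose resolution is bounded
by the record count rather than by total simulated time.

## 2. Network reconstruction

Fifteen regulations are named in the source text's sensitivity analysis.
Two reconstruction choices were required:

* **OCT4 -| miR145.** The sensitivity-control list prints an activation,
  but the narrative consistently writes the edge as a repression
  (OCT4 -| miR145 chains), and only the repression reading is consistent
  with the printed count of seven activations and nine repressions. We use
  the repression.
* **The 16th edge is P53 -| OCT4.** The binding-reaction example in the
  source's Methods explicitly describes the P53 protein binding a
  *repressing* site of the OCT4 gene. That edge appears in no other list;
  adding it gives exactly 16 regulations with the 7/9 sign split. (The
  biological reading — P53 antagonizes stemness — is standard.)

## 3. Kinetic calibration (the central reconstruction)

The published per-site binding/unbinding constants ($h_1, h_2, h_3$,
$f_1, f_2, f_3$ per site type) were defined only in supplementary material
that is not available. The caption-level summary rates $h_a = 2$,
$h_r = 1.875$ **cannot** be the per-site propensity coefficients: with
$f = 1000$ the occupancy threshold of a site (the source copy number at
which binding and unbinding balance) is then ~500 (monomer), ~32 (dimer)
or ~7 (tetramer), while expression ranges span 25–400. Every site is
either saturated or inert across the whole operating range, and the system
is provably monostable: we verified this by adiabatic mean-field
fixed-point analysis (exhaustive over uniform multimer orders, exhaustive
over per-source-species assignments, and hill-climbing over the full
$3^{16}$ per-site space — all yield a single fixed point), and by direct
simulation. The published system has seven attractors, so the
supplement-only constants must differ from the caption summary.

The shipped default network therefore derives each site's binding rate
from an **occupancy threshold** $n^\*$ — the source copy number at which
the site is half occupied — via `site_rate_for_threshold()`
($h = f / \binom{n^\*}{m}$-type inversion of the mass-action law). All
sites are tetramers, the steepest law in the published reaction scheme
(the response sharpness of a site is $\sim$ Hill-$m$; dimer steepness
cannot hold an OFF state against an 8-fold activation). Thresholds were
placed by Boolean-limit analysis of the seven published expression
signatures — each threshold bisects the OFF/ON levels of its source in
the states that site must discriminate — then refined by a stochastic
lifetime screen (six states simulated from their candidate centers; a
configuration passes when each survives the test horizon). The frozen
values are in `grnlandscape:::default_site_thresholds()`. Two thresholds
do the heavy lifting: P53→miR145 and MDM2-|P53 at 350 copies create the
three-level P53 axis (normal/premalignant/low), and ZEB→ZEB at 90 with
miR200-|ZEB at 30 creates the three-level ZEB axis.

This calibration targets only the *qualitative* published structure
(which attractors exist and their low/intermediate/high signatures).
Printed barrier heights, transition times and fluxes were never used as
calibration targets; the package measures them and reports what it finds.

**Level thresholds.** Basin labeling discretizes each axis into
low/intermediate/high. The generic default is support-range tertiles
(`label_basins(thresholds = NULL)`); the shipped pipeline configuration
pins absolute cuts between the calibration's designed expression levels —
P53 (150, 305), ZEB (100, 215), OCT4 (140, 300) — because support-range
tertiles are inflated by transient tails at desk-scale sampling.

**Known limitation (CSC).** The reconstruction sustains a persistent
intermediate state with reduced P53 and elevated ZEB — the biological
analog of the cancer stem cell state — but its OCT4 level is high, not
intermediate: with this wiring OCT4 has no repressor available in that
state (miR-145 is doubly repressed there), and an OCT4-intermediate fixed
point would sit on the unstable branch of its self-activation switch. The
published all-intermediate CSC signature therefore remains unmatched and
the corresponding acceptance check fails honestly; see the decisions
ledger. The same applies to barriers/fluxes along routes through CSC.

## 4. Sampling strategy and what a green test establishes

The circuit is deeply metastable: single-start desk-scale trajectories
never cross the larger barriers, so pooled occupancy from one initial
condition misses whole basins. The pipeline therefore pools time-weighted
occupancy from an ensemble started at the 8 low/high corners of the
marker axes plus one all-intermediate point (`dispersed_inits()`),
non-marker species starting at basal level $g_0/k$ (they relax within
$\sim 1/k$). Consequences, stated plainly:

* every attractor with a dwell time beyond the burn-in is discovered and
  its **within-basin** shape (hence barrier *differences on a path*) is
  sampled;
* **cross-basin weights** (relative `P_mass`, absolute $U$ differences
  between distant minima) converge to the stationary law only in the
  long-run limit; at desk scale they reflect the start distribution and
  run length. Barrier values are therefore budget-dependent; basin
  *identity* and barrier *rank structure* are the robust desk-scale
  outputs.

Defaults: bin width 5 copies, Gaussian smoothing of 1 bin (kernel
truncated at 4 sd, renormalized), watershed on 6-connectivity with
persistence merging at 0.5 $U$-units (below the sampling noise of
$-\ln P$ at achievable statistics), desk budget 18 runs × 2600 time units
(~1.6 × 10^9 events, about two minutes of wall time). The run length is
chosen so that the faster inter-basin transitions (lifetimes of order
1–4 × 10^3 time units at this calibration) occur within the budget,
connecting the sampled support along real transition paths; pairs whose
transitions are slower than the budget remain disconnected and report
infinite barriers rather than extrapolated ones.

## 5. Kinetics

Saddles between basins are minimax levels: an ascending union-find sweep
over the support graph yields, for every pair of minima, the lowest level
at which they connect — exactly the minimax over grid paths of the
maximal $U$, validated against exhaustive widest-path enumeration on
small grids. Barrier(A→B) = $U$(saddle) − $U_\min$(A), so the
shared-saddle identity holds by construction. Disconnected pairs get
infinite barriers.

MFPTs are means of direct first-passage simulations from the source
minimum (sites unbound, no re-equilibration) into the target basin core
(its voxels within $\delta_\text{core} = 1$ $U$-unit of the target
minimum). Passages exceeding the event budget are censored and excluded;
estimates with more than 10% censoring are flagged unreliable. Path flux
follows the sequential-MFPT reconstruction: route time = sum of step
MFPTs, rate = 1/time, flux = stationary source probability × rate,
probabilities = fluxes normalized over the supplied routes. Raw flux
magnitudes inherit the cross-basin weight caveat of Section 4; route
*probabilities* (ratios) are the validated quantity.

## 6. Sensitivity

"Regulation strength" multiplies the binding rate $h$ of one regulation
(equivalently divides its $X_{eq} = f/h$); `scale_lambda = TRUE` offers
the alternative fold-change semantics. Each scan point re-runs the
landscape/barrier pipeline on a fixed seed ladder with exactly one
`strength_scale` changed; deltas are relative to scale 1.0; a basin
missing at some scale is recorded as such and the scan continues. Scan
budgets are reduced relative to the headline landscape; the acceptance
checks ask only for reproducible *signs* across seed ladders.

## 7. Synthetic expression data

The generator stands in for the bulk RNA-seq comparison (the original
used tumor cohorts we neither download nor emulate in depth). It draws
samples from latent states: 40 genes in three groups (18 cancer/P53, 11
EMT/ZEB, 11 stemness/OCT4), gene value = state coordinate × positive
loading + Gaussian noise, truncated at zero. It emulates *only* the
structure the comparison needs — state-dependent group means recoverable
by group-wise PCA — and none of the features of real tumor data (counts,
library size, batch, dropout, correlated genes beyond rank-1 groups). A
green recovery test establishes that the analysis pipeline (group PCA →
silhouette-selected k-means → nearest-center basin matching after per-set
standardization) recovers planted structure, nothing more. Noise default
0.4–0.5 on unit-scale centers ≈ separation-to-noise ratio of ~3, a
realistic regime for well-separated expression phenotypes.

## 8. Numerical choices and degenerate inputs

* RNG: R's stream, seeded per trajectory; child seeds derive
  deterministically from a master seed (`derive_seeds()`); every output is
  bitwise reproducible given (config, seed).
* The running total propensity is refreshed every $2^{20}$ events to
  bound floating-point drift; a drift-triggered selection miss re-syncs
  and retries instead of firing an arbitrary reaction.
* Absorbing states (total propensity 0) are signalled, and their dwell
  time is credited to the occupancy histogram up to `t_max`.
* Ties in $U$ during watershed are broken by voxel index after radix
  ordering; a flat landscape yields a single basin.
* The truncated master-equation solver (`solve_cme_reference`, a testing
  oracle) uses reflecting truncation and warns when boundary mass exceeds
  tolerance.
* `barrier_time_correlation` refuses zero-variance inputs and fewer than
  3 pairs.

## 9. Configuration profiles

`run_config("desk")` finishes in minutes on one CPU: basin structure is
retained; barrier values are noisier and cross-basin weights are
start-biased (Section 4). `run_config("paper")` is the headline budget
(hours-scale) with more and longer runs and larger MFPT budgets. All
analyses accept any wiring via JSON network files
(`inst/extdata/config_schema.md`).
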