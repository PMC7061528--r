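# grnlandscape

Stochastic potential-landscape analysis of a six-node gene regulatory
circuit coupling three cancer-relevant programs: the P53/MDM2 tumor-suppressor
axis, the ZEB/miR-200 epithelial-mesenchymal transition (EMT) switch, and the
OCT4/miR-145 stemness module. The package is written for computational
systems biologists who want to reproduce, perturb, or extend
binding-site-resolved landscape analyses of small gene circuits.

## The model

Each of the 6 species (P53, MDM2, ZEB, OCT4, miR-145, miR-200) is a copy
number n_i; each of the 16 regulations contributes one binding site on its
target promoter. The chemical reactions are

* synthesis: gene_i -> gene_i + X_i at rate g0 * prod(lambda over bound
  sites), with lambda_a = 8 for bound activators and lambda_r = 0.5 for
  bound repressors (a gene with n sites has 2^n synthesis rates),
* degradation of free copies at rate k * n (k = 1),
* binding of an m-mer of the source at rate h*n (monomer),
  h*n(n-1)/2 (dimer), or h*n(n-1)(n-2)(n-3)/6 (tetramer), sequestering m
  copies,
* unbinding at rate f = k * omega, with adiabaticity omega = 1000
  (fast site equilibration).

The chemical master equation dP/dt = (M0 + Mb) P is solved by exact
Gillespie simulation (compiled inner loop, ~10^7 events/s); the potential
landscape is U = -ln P over the (P53, ZEB, OCT4) marginal. Basins of U are
the stable cell phenotypes: normal, premalignant, cancer, stem cell (SC),
cancer stem cell (CSC), lesion, and hyperplasia. Barrier heights are minimax
saddle levels on the discretized landscape; transition times are mean
first-passage times (MFPT) of direct simulations; multi-step routes between
normal and cancer are compared by path flux (stationary source probability
times the reciprocal summed MFPT). One-at-a-time scaling of a regulation's
binding rate quantifies which interactions control the barriers.

Because the published per-site rate constants were supplementary-only (the
headline rates make the circuit provably monostable), the default network
uses a documented reconstruction: tetramer sites whose binding rates are
derived from occupancy thresholds placed between each source's OFF and ON
levels (`site_rate_for_threshold()`, thresholds in
`grnlandscape:::default_site_thresholds()`). See the methods vignette
(`vignettes/landscape-methods.Rmd`) for the derivation and its limits.

## Worked example

```r
library(grnlandscape)

net <- default_network()          # 6 nodes, 16 regulations, omega = 1000
validate_network(net)             # character(0)

cfg <- run_config("desk", seed = 1)     # minutes-scale budget
res <- run_all(cfg, stages = c("simulate", "landscape"), quiet = TRUE)
res$basins$summary[, c("U_min", "P53", "ZEB", "OCT4", "label")]
```

On the desk budget (18 dispersed-start trajectories, t_max 2600, ~3 min on
one CPU) this prints the detected attractors (seed 1):

```
  U_min  P_mass   P53   ZEB  OCT4        label
1 7.302 0.11019 367.5  12.5  42.5       normal
2 7.456 0.06110  52.5  27.5  52.5       lesion
3 8.002 0.15328  52.5 192.5 387.5   unassigned
4 8.181 0.11071  52.5 247.5  52.5       cancer
5 8.254 0.16188 277.5 182.5  52.5 premalignant
6 8.269 0.05753  52.5  27.5 387.5  hyperplasia
7 8.398 0.23415 252.5 192.5 382.5   unassigned
8 8.427 0.11105 347.5  17.5 362.5           SC
```

`U_min` is the basin depth in -ln P units (smaller = more occupied),
`P_mass` the desk-scale occupancy share, the coordinates are the basin
minima in copy numbers, and labels follow the low/intermediate/high
signatures of the seven cell states. Basin 7 is the persistent
intermediate state (reduced P53, elevated ZEB, high OCT4) — the
cancer-stem-cell analog of this reconstruction; it stays `unassigned`
because the published CSC signature expects intermediate OCT4 (see the
methods vignette). Basin 3 is its low-P53 twin.
Barriers, MFPTs and fluxes continue from the same object:

```r
bm <- barrier_matrix(res$grid, res$basins)
lab <- c("normal", "premalignant", "cancer", "SC", "lesion", "hyperplasia")
bm <- bm[is.finite(bm$barrier) & bm$from %in% lab & bm$to %in% lab, ]
bm[order(bm$barrier), c("from", "to", "barrier")]
```

which prints (same run; pairs whose inter-basin transitions were not
sampled at this budget report `Inf` and are filtered):

```
          from           to barrier
1       cancer       lesion    7.71
2 premalignant       lesion    7.89
4 premalignant       cancer    7.89
6       cancer premalignant    7.96
3       lesion       cancer    8.44
5       lesion premalignant    8.69
```

## Command line

```sh
inst/cli/grn-landscape network validate inst/extdata/network_paper.json
inst/cli/grn-landscape network show default
inst/cli/grn-landscape simulate default --t-max 100 --seed 1 --out traj.tsv
inst/cli/grn-landscape run inst/extdata/config_desk.json
```

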