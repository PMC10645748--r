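# kvclust

Ion-channel cluster assembly, quantal sparklet activity, and current-density
scaling in arterial myocytes.

## What this package is for

In arterial smooth muscle, KV2.1 channels self-assemble into micro-clusters
that can coalesce into large macro-clusters when the channel's C-terminal
clustering domain is phosphorylated. Macro-clustering is more extensive in
female than male myocytes, and it tunes the clustering and cooperative
gating of neighboring CaV1.2 channels — and hence Ca²⁺ influx — while
leaving KV2.1's own K⁺ conduction essentially unchanged. `kvclust` gives
quantitative cell physiologists a tested, reproducible implementation of the
computational methods such studies rest on:

* **Stochastic self-assembly** — a lattice model in which empty sites
  nucleate with probability `p_n`, sites adjacent to a cluster are occupied
  with `p_g`, and occupied sites are removed with `p_r` (synchronous
  updates, periodic boundaries). Its steady states reproduce the
  single-exponential cluster-size distributions seen in imaging data, and
  `fit_params()` recovers generating parameters from observed distributions
  by replicate-averaged grid search.
* **Cluster segmentation and classification** — fixed-threshold 3D
  connected-component segmentation (26-connectivity, >2-voxel rule, 100 nm
  lateral / 150 nm axial minima), per-cell metrics (counts, volumes, %
  membrane occupancy), exponential size-law fits
  `count = A·exp(−V/τ)`, and the macro/micro boundary
  `V_macro = mean − 2·SD` (0.06 µm³ for mean 0.12, SD 0.03), with strict
  classification `V > V_macro`.
* **Super-resolution rendering** — per-frame 2D Gaussian localization of
  blink movies, 20 nm/pixel rendering, and the intensity-conserving 200 nm
  Gaussian blur that makes groups of micro-clusters coalesce into
  confocal-style macro-clusters.
* **Quantal sparklet analysis** — idealization of 100 Hz fluorescence traces
  into integer quantal levels, site activity `nPs = Σ_k k·T_k / T` with the
  0.2 low/high cutoff, and maximum-likelihood estimation of the coupling
  coefficient κ under a coupled Markov chain
  `P = (1−κ)·P_indep + κ·P_sync` (κ = 0: independent gating; κ = 1:
  simultaneous opening and closing).
* **Current-density prediction** — linear scaling of 100%-functional
  reference IV densities by a functional fraction `f`, and
  blocker-subtraction analysis of voltage-step recordings.

Every input has a synthetic generator with known ground truth
(`gen_cluster_population()`, `render_image_stack()`, `gen_sparklet_trace()`,
`gen_blink_movie()`), so the whole chain is verifiable by recovery.

## Worked example

Classify a synthetic cluster population against the macro/micro threshold
and estimate gating coupling from a simulated sparklet site:

```r
library(kvclust)

# macro/micro boundary from the canonical mean and SD
thr <- macro_threshold(0.12, 0.03)
thr$threshold                 # 0.06  (um^3)
round(thr$equivalent_diameter_nm)  # 486 (sphere-equivalent)

# exponential population with mean 0.07 um^3: expect exp(-0.06/0.07) = 0.42 macro
pop <- gen_cluster_population(cluster_spec(10000, 0.07, seed = 1))
classify_macro_micro(pop, thr)$macro_fraction   # 0.4178

# coupled sparklet site: simulate, idealize, estimate
sim <- gen_sparklet_trace(sparklet_spec(n_channels = 3, kappa_true = 0.4,
                                        open_prob = 0.1, noise_sd = 0.2,
                                        duration = 20, seed = 1))
rec <- detect_and_idealize(sim$trace, quantal_config(1, max_levels = 3))
compute_nps(rec)$nPs          # 0.298 -> "high" (cutoff 0.2)
estimate_kappa(rec, 3)$kappa  # 0.395 (2000 frames; RMSE ~0.02 over 20 sites)

# current densities with half the channels functional
scale_current(myocyte_reference_iv("male"), 0.5)$reported_density    # 3503 pA/pF
scale_current(myocyte_reference_iv("female"), 0.1)$reported_density  # 1729 pA/pF
```

The numbers above are what the code prints: the macro fraction matches the
exponential tail probability to sampling error; a single 2000-frame site
estimates κ with an RMSE of ~0.03, and the mean over 20 sites lands within
±0.02 of the truth (see `analysis/03_sparklet_coupling.R`).

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the package over
its generators and write tables under `results/`:

| script | what it computes |
| --- | --- |
| `01_cluster_size_distributions.R` | exponential size-law fits, macro/micro fractions, segmentation round trip |
| `02_assembly_steady_state.R` | steady-state lattice distributions in two regimes, exponential-tail R², parameter recovery |
| `03_sparklet_coupling.R` | nPs and κ recovery across the coupling range |
| `04_current_scaling.R` | functional-fraction density table, blocker-subtraction demo |

Each is run as `Rscript analysis/01_cluster_size_distributions.R` from the
repository root.

## Methods

The model definitions, parameter conventions, numerical choices, and
limitations are documented in
`vignettes/channel-cluster-analysis.Rmd`.
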