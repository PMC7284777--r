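---
title: "Methods: cell networks, release kinetics, SERS chemometrics and surface topography"
author: "theranosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell networks, release kinetics, SERS chemometrics and surface topography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(theranosim)
```

`theranosim` bundles the four computational analyses needed to characterise a
gold-functionalised mesoporous-silicon cell-theranostic chip: spatial network
analysis of cultured cells, first-order drug-release kinetics, SERS
hyperspectral chemometrics, and nanoscale surface topography. Because raw
micrographs, spectra and release tables from such experiments are rarely
deposited, the package ships a synthetic-data module that generates every
input with planted ground truth; all validation in the test suite is against
that planted truth. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic validation does and
does not establish.

## Cell spatial networks

### From image to nodes

A DAPI fluorescence image is reduced to candidate cell positions in three
steps:

1. **Segmentation** (`segment_image()`). The image is low-pass filtered
   (Gaussian, sd 1 px — the exact denoising filter is not critical for a
   threshold-based pipeline), contrast-stretched to [0, 1], and partitioned
   into `k` intensity classes by one-dimensional k-means. The `t` classes on
   the background side are set to 0, the rest to 1. Defaults `k = 3`,
   `t = 1`: a dark background class, a blob-periphery class, and a bright
   core class, with the two brighter classes kept as foreground. Nuclei are
   bright on a dark background in DAPI imaging, so the darkest class is
   background by default; an `invert` flag covers the opposite polarity.
   The 1-D k-means is deterministic (quantile-seeded Lloyd iterations on the
   unique intensity values), so segmentation carries no RNG state.
2. **Occupancy downsampling** (`downsample_occupancy()`). The binary mask is
   averaged over non-overlapping `r` × `r` pixel blocks, where `r²`
   approximates the area of one nucleus in pixels (`r = 6` at 1.72 µm/px for
   ~10 µm nuclei). Partial edge blocks are averaged over their true pixel
   count, which makes the block-size-weighted mean of the occupancy grid
   equal the mask's foreground fraction *exactly* — a conservation identity
   the tests assert.
3. **Node detection** (`detect_nodes()`). Every block whose occupancy
   probability exceeds `p_thresh` becomes one node at the block centre.

`p_thresh` defaults to 0.48. This was calibrated once against synthetic
images with planted positions: at 0.5 the clustered layouts lose ≈ 6–7 % of
cells to block merging while isolated nuclei that straddle block corners are
also lost; 0.48 balances merge losses against straddle-split gains and holds
the median count error at 2–3 % for both clustered and uniform layouts. It
was then frozen.

### The Waxman graph

Detected nodes are connected by the Waxman rule: the connection probability
between nodes at Euclidean distance $d$ is
$P = \alpha e^{-d/(\beta L)}$ with $\alpha = 1$, $\beta = 0.025$, and $L$
the largest possible distance between two grid nodes. Applying the decision
rule $\alpha e^{-d/(\beta L)} - R \ge 0$ with the constant $R = 0.1$ makes
connectivity deterministic: nodes are linked exactly when
$d \le d^* = \beta L \ln(\alpha/R)$. Two choices deserve comment:

* **Deterministic rule, not Bernoulli sampling.** The decision-rule form is
  a hard distance threshold; the stochastic reading of the probability
  formula is not implemented. (Note the source description of $R = 0.1$
  "so that the probability of being a connection is 0.9" is internally
  inconsistent — the rule as written connects whenever $P \ge 0.1$; we
  implement the rule literally.)
* **$L$ from the field extent.** $L$ is the diagonal of the field of view,
  computed from the image geometry rather than from the realised nodes, so
  that sparse detections do not silently shrink the cutoff. For the default
  1174 × 882 µm field, $d^* = 0.025 \times 1468\,\mu m \times \ln 10
  \approx 84.5\,\mu m$.

### Topology metrics

* `clustering_coefficient()` — Watts–Strogatz local clustering averaged over
  nodes, degree < 2 contributing 0 (the standard convention; backed by
  igraph and verified against a brute-force triangle count on all small
  graphs).
* `characteristic_path_length()` — mean shortest-path **hop count** over
  reachable pairs. Hop counts (not µm) are used: reported path lengths of
  order 2–8 in this field are consistent with hop metrics. Restricting to
  reachable pairs keeps the quantity finite on fragmented layouts; an
  infinite-distance convention would make any disconnected culture
  unreportable.
* `er_null_metrics()` — an Erdős–Rényi G(n, m) ensemble (exact edge count,
  20 replicates by default, seeded) supplies $Cc_{rand}$ and $Cpl_{rand}$;
  `small_world_ness()` combines them as
  $SW = (Cc/Cc_{rand}) / (Cpl/Cpl_{rand})$.

A caution on magnitudes: any geometric graph has local clustering of order
0.6 while a same-density ER graph has $Cc_{rand} = 2m/(n(n-1)) \approx$
0.02–0.05, so SW values for spatial cell graphs are generically ≫ 1 under
this definition. Comparisons between substrate morphologies should therefore
be made on paired layouts of equal cell count, which is what the package's
tests do; absolute SW values depend strongly on the null convention.

## The synthetic nuclei generator

`simulate_nuclei_image()` draws positions either i.i.d. uniformly or from a
Thomas cluster process (uniform parents, isotropic Gaussian offspring with
toroidal wrapping, keeping the count exact and the density stationary).
Cells are rendered as Gaussian blobs (sd = `nucleus_radius`, default 3 µm,
i.e. an apparent nucleus ≈ 10 µm across) on a constant background with
additive Gaussian noise. No PSF, photon noise, or 3-D structure is
simulated: the downstream pipeline is threshold-based, and these omissions
are deliberate. Passing tests on this generator demonstrate that the
pipeline recovers *planted geometry under idealised imaging*; they do not
certify segmentation accuracy on real micrographs with uneven illumination
or out-of-focus nuclei.

Colony compactness is the single most influential generator parameter, and
it pulls two validation goals in opposite directions:

* **Count recovery.** With colonies of ~20 cells spread with
  `cluster_sd = 40` µm (sub-confluent, nuclei mostly resolvable at the
  block scale) the detector recovers planted counts to ≤ 5 % median error.
  These are the generator defaults (`n_cells = 200`, `n_parents = 10`,
  `cluster_sd = 40`).
* **Network contrast.** The small-world contrast between clustered and
  uniform cultures is strongest for *confluent* colonies
  (`cluster_sd = 20` µm, `n_cells = 650` — cell numbers in the range
  observed on adhesive substrates): compact, well-separated colonies have
  intra-colony path lengths near 1 and beat their ER null, while uniform
  spreads pay a large path-length penalty. In that regime the occupancy
  detector undercounts (nearly-touching nuclei merge at the block scale) —
  a genuine resolution limit of occupancy-based detection, not a bug. The
  network-comparison tests therefore use the confluent parameterisation
  explicitly, and the count-recovery tests use the resolvable one. Both
  parameter sets are fixed in the test suite and documented here.

## Drug-release kinetics

Cumulative release into a stirred bath follows
$c(t) = c_0 + c_s(1 - e^{-t/\tau})$, with $c_s$ the steady-state
concentration increment (µM) and $\tau$ the time constant (h) — the time to
reach $1 - e^{-1} \approx 63.2\%$ of the final increment. (Descriptions of
$\tau$ as the time to "66 %" of the final value are rounded folklore; the
implementation uses the exact exponential constant.) `fit_release()` fits by
Levenberg–Marquardt least squares with bounds $c_s \ge 0$, $\tau > 0$,
initialised at $c_s^0 = \max c - \min c$ and $\tau^0 =$ the first time the
curve exceeds $c_0 + 0.63\,c_s^0$. $c_0$ is fixed at 0 by default (release
into initially drug-free water); `fix_c0 = FALSE` frees it. Constant curves
are returned with $c_s = 0$ and an explicit "tau unidentifiable" flag rather
than a silently arbitrary time constant.

Derived quantities:

* `initial_velocity()` — first-order Taylor expansion at $t = 0$ gives the
  early release rate $v = c_s/\tau$ (µM/h), identical to the analytic slope
  $c'(0)$.
* `release_efficiency()` — $c(t)/c_{load}$ and the asymptote
  $c_s/c_{load}$.
* `drug_efficacy()` — from adhering-cell counts,
  $E = 1 - N_{drug}/N_{ctrl}$: the fraction of cells suppressed relative to
  the drug-free control. (The complementary bare ratio
  $N_{drug}/N_{ctrl}$ is sometimes *described* in prose where the
  suppressed fraction is plainly what is tabulated; the package implements
  the suppressed fraction, which reproduces all published worked examples.)
* `half_life_extension()` — the sustained-release duration over a drug's
  intrinsic elimination half-life, as fold and percent increase.

Validation: noiseless fits recover generating parameters to solver
tolerance; with 5 % relative Gaussian noise on 30 points, the median
relative error of $(c_s, \tau)$ over 50 seeds is ≤ 5 %.

## SERS chemometrics

`simulate_sers_map()` plants two spectral classes on a 0.5 µm grid over
700–3250 cm⁻¹: both carry cell fingerprint bands (1126, 1175, 1306, 1506,
1645 cm⁻¹) on a broad fluorescence hump; "adhesion" pixels additionally
carry a Lorentzian band at 1569 cm⁻¹ — the tryptophan frequency used as an
integrin marker.

The analysis chain is: `area_normalize()` (each spectrum divided by its
trapezoidal integral, the standard fluorescence-suppression step; zero-area
spectra are excluded with a warning, never silently zeroed),
`fit_pca()` (mean-centred; five components by default), `cluster_pixels()`
(k-means on the scores, best of 10 restarts, five classes by default), and
`loading_ratio()`:

$$r = \frac{\max_{|\nu - 1569| \le w} |l(\nu)|}{\overline{|l|}}$$

on the first component's loading. Choices: absolute values (the loading
sign is arbitrary; PCA signs are fixed deterministically by making the
largest-magnitude loading element positive, so results are reproducible),
window half-width $w$ = 5 cm⁻¹ with max-in-window (robust to axis
discretisation), and PC1 (the component carrying most spectral variance).
A flat loading gives $r = 1$ exactly; planted-band maps give $r \gg 2$.

Published per-substrate $r$ values and explained-variance figures derive
from undeposited spectra and are not reproducible targets; the tests
validate the pipeline on planted classes instead (Rand index > 0.9 against
ground truth over 10 seeds).

## Surface topography

* `roughness_Ra()` — arithmetic roughness: mean |height − mean plane| after
  least-squares linear detrend. Taken as arithmetic (not RMS) at face
  value. Closed-form check: a sine of amplitude $A$ has $Ra = 2A/\pi$.
* `power_spectrum()` — linear detrend, Hann window (switchable to `"none"`,
  in which case the total 2-D power equals the detrended height variance
  exactly — Parseval), periodogram, radial average into 26 logarithmic
  frequency bins. Each bin records how many Fourier modes it averaged.
* `fractal_dimension()` — weighted log–log fit of binned power versus
  frequency (weights = modes per bin, since a periodogram bin's sampling
  variance scales as 1/n_modes; without weighting the sparse low-frequency
  bins dominate the scatter). The self-affine convention for isotropic 2-D
  surfaces is fixed as $P(q) \propto q^{-(8 - 2D_f)}$, i.e.
  $D_f = (8 - \beta)/2$ from slope $-\beta$, clamped to [2, 3]. The default
  fit band drops the two lowest bins (detrend leakage) and the top octave
  (discretisation floor); fits with $R^2 < 0.8$ are flagged low-confidence
  rather than rejected. `simulate_fractal_surface()` synthesises surfaces
  by filtering white noise with the matching $q^{-\beta/2}$ amplitude, so
  the round trip is self-consistent by construction: recovering planted
  $D_f \in \{2.15, 2.48\}$ within ±0.1 at a 512² grid validates estimator
  and convention together, not the convention against an external standard.
* `porosity()` / `segment_pores()` — void fraction of a binary image; the
  grayscale-to-binary step is an automatic Otsu threshold with dark = void.
  This thresholding + connected-components procedure is a documented
  reconstruction of a standard micrograph porosity workflow; published
  porosity and particle-size values from real SEM images are not used as
  exact tests.
* `feature_size_stats()` — 8-connected components, equivalent-circle
  diameter $2\sqrt{A/\pi}$, border-touching components excluded to avoid
  truncation bias. Touching features merge — documented behaviour of
  connectivity labelling, relevant when sizing densely packed
  nanoparticles.

## Reproducibility and problem sizes

Every stochastic operation takes an explicit seed and restores the caller's
RNG state (`withr::with_seed`); identical inputs give bit-identical outputs.
`run_pipeline()` executes all five synthetic stages from one seeded
configuration, writes CSV/JSON outputs plus a provenance record, and is
exactly reproducible.

The validation suite uses problem sizes chosen to exercise each estimator in
its operating regime while keeping the full suite around a minute: 500
exhaustively-checked graphs of ≤ 8 nodes, 1000 random node sets for the
Waxman rule, 10 paired 650-cell fields for the morphology contrast, 50
noisy release fits, 512² surfaces for fractal recovery, and 512² porous
images. Larger fields change none of the conclusions, only the runtime.

## Known limitations

* Occupancy-based node detection undercounts confluent colonies by design;
  instance segmentation (e.g. watershed) would be needed to resolve
  touching nuclei, and is out of scope.
* SW magnitudes depend on the null-model convention (see above); only
  paired comparisons are meaningful outputs of this package.
* The synthetic SERS baseline is spatially uniform; real maps have
  pixel-dependent fluorescence that area normalisation only partly removes.
* The release model is empirical first-order kinetics; no Fickian transport
  PDE is solved.
* Fractal-dimension estimates assume an isotropic, self-affine surface over
  the fitted band; anisotropic textures violate the radial-average premise.
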