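# theranosim

Characterisation pipeline for cell-theranostic mesoporous silicon
substrates — chips that simultaneously culture cells, release a drug from
their pore network, and act as SERS sensors for cell-adhesion molecules.
Evaluating such a device requires four computational analyses that this
package implements as one tested R toolbox, together with a synthetic-data
module that generates every input with planted ground truth:

1. **Cell spatial networks.** Fluorescence images of DAPI-stained nuclei are
   segmented by 1-D k-means, downsampled into an occupancy grid of one-cell
   blocks, and thresholded into graph nodes. Nodes are connected by the
   Waxman rule — connect nodes at distance *d* iff
   α·e^(−d/(βL)) − R ≥ 0, i.e. *d* ≤ d\* = βL·ln(α/R), with α = 1,
   β = 0.025, R = 0.1 — and scored by the clustering coefficient *Cc*, the
   characteristic path length *Cpl* (hop counts over reachable pairs), and
   small-world-ness SW = (Cc/Cc_rand)/(Cpl/Cpl_rand) against a G(n, m)
   Erdős–Rényi null of equal nodes and edges.
2. **Drug-release kinetics.** Concentration–time curves are fitted with the
   first-order model c(t) = c₀ + c_s(1 − e^(−t/τ)); derived outputs are the
   early release velocity v = c_s/τ, the release efficiency c(t)/c_load,
   drug efficacy from adhering-cell counts E = 1 − N_drug/N_ctrl, and the
   half-life extension of a sustained-release configuration.
3. **SERS chemometrics.** Hyperspectral Raman maps are area-normalised,
   decomposed by PCA, clustered by k-means into chemometric classes, and
   scored by the integrin loading-ratio r = max|loading| at 1569 cm⁻¹ over
   the mean |loading| across the spectrum.
4. **Surface topography.** Arithmetic roughness Ra, the radially averaged
   power spectral density with fractal dimension D_f = (8 − β)/2 from its
   log–log slope −β, porosity (void fraction) of thresholded micrographs,
   and equivalent-diameter statistics of particles/pores.

See the methods vignette (`vignettes/theranosim-methods.Rmd`) for the
models, parameter defaults, and numerical conventions.

## Worked example

```r
library(theranosim)

# --- cell network from a synthetic 1174 x 882 um field of 200 nuclei
sim <- simulate_nuclei_image(nuclei_layout_params(n_cells = 200, seed = 1))
analyze_image(sim$image, seed = 2)
#> <graph_metrics>
#>   N   = 196 nodes, 1476 edges
#>   Cc  = 0.8241  (ER null 0.0774 +/- 0.0038)
#>   Cpl = 2.2766  (ER null 2.2105 +/- 0.0038)
#>   SW  = 10.3437
```

196 of the 200 planted cells are recovered; the clustered culture's local
clustering (0.82) is far above its random-graph reference at near-identical
path length, giving SW ≫ 1 — the small-world signature of colony-forming
cells.

```r
# --- release kinetics: fit a noisy synthetic curve and report the velocity
curve <- simulate_release_curve(release_model_params(cs = 4.94, tau = 46),
                                times = seq(0, 240, by = 8),
                                noise_sd = 0.25, seed = 3, c_load = 30)
fit_release(curve)
#> <release_fit>
#>   c0 = 0 uM, cs = 4.895 uM, tau = 46.22 h (v = 0.1059 uM/h)
#>   RSS = 1.231 over 31 points

drug_efficacy(c(675, 451, 362), c(1871, 2928, 3962),
              substrate = "MeP1", time_h = c(36, 48, 72))$E
#> [1] 0.6392304 0.8459699 0.9086320
```

The fit recovers the generating parameters (c_s = 4.94 µM, τ = 46 h) within
1 %, giving an early release velocity c_s/τ ≈ 0.11 µM/h; the efficacy
column shows the fraction of cells suppressed by the released drug rising
from 0.64 to 0.91 over three days.

```r
# --- SERS map with a planted 1569 cm-1 integrin band in half the pixels
m <- simulate_sers_map(seed = 4)
pca <- fit_pca(area_normalize(m))
loading_ratio(pca)
#> <integrin_ratio> r = 65.143 at 1569 cm-1 (+/- 5, PC1)

# --- fractal surface round trip
surf <- simulate_fractal_surface(
  surface_synthesis_params(target_Df = 2.48, target_Ra = 7, seed = 5))
fractal_dimension(power_spectrum(surf))
#> <fractal_fit> Df = 2.488 (slope -3.023, R^2 = 0.999) over 20 bins
porosity(simulate_porous_image(0.12, seed = 6))
#> [1] 0.1150208
```

The planted spectral band dominates the first principal component
(r ≫ 2); the planted fractal dimension 2.48 and porosity 0.12 are
recovered within 0.01.

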