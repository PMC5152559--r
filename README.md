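# lesionnet

Functional connectome construction and lesion network analysis for
parcel-level BOLD time series.

`lesionnet` implements the graph-theoretical pipeline used to characterise
resting-state functional brain networks in patients with focal lesions
(e.g. glioblastoma), from time series to surgical "connections-at-risk"
maps. It targets the common study geometry of an AAL-style 116-parcel
template (45 regions per cerebral hemisphere, 26 cerebellar/vermis) and
scans of 269 volumes at TR = 2.42 s, but every step is parameterised.

## What the pipeline computes

1. **Wavelet decomposition.** Each parcel's series is decomposed with the
   maximal overlap discrete wavelet transform (MODWT, Daubechies
   least-asymmetric length-8 filter, reflection boundary). Scale *j*
   covers the dyadic band [f_N/2^j, f_N/2^(j-1)] with f_N = 1/(2·TR); at
   TR 2.42 s the five scales map to ≈0.2–0.1, 0.1–0.05, 0.05–0.03,
   0.03–0.01 and 0.01–0.006 Hz.
2. **Wavelet correlation.** Pearson r_ij between all parcel pairs per
   scale, over non-boundary coefficients only; per-edge group averaging
   across subjects.
3. **Thresholding.** The mean degree is fixed at k_net = 2·ln(n) (9.5 for
   n = 116), i.e. the m = round(n·ln n) = 551 strongest correlations
   (≈8 % of the 6670 possible edges) are kept — *provided* every retained
   edge also survives Benjamini–Hochberg FDR control at α = 0.05. Scales
   that cannot reach the required mean degree significantly are declared
   inadmissible and excluded.
4. **Graph metrics.** Degree, clustering, nodal path length, global
   efficiency, information centrality (percentage change in global
   efficiency upon single-node removal, fixed-denominator convention so an
   isolated node scores exactly 0), giant component, and hub tables.
   Small-world indices γ = C_net/C_random, λ = L_net/L_random and
   δ = γ/λ are normalised against Maslov–Sneppen degree-preserving
   rewired nulls.
5. **Degree-distribution model selection.** Discrete maximum-likelihood
   fits of an exponential, a power law and an exponentially truncated
   power law P(k) ∝ k^(α−1)·e^(−k/k_c), compared by AIC with the
   conventional parsimony rule (most parsimonious model within 2 AIC
   units of the minimum).
6. **Robustness.** Random-error and targeted-attack node-removal curves
   (giant component and efficiency relative to the intact network),
   compared against degree-matched rewired and scale-free null families.
7. **Lesion reporting.** Edges incident to tumour-adjacent parcels,
   classified as intra-lobar / intra-hemispheric / inter-hemispheric and
   contrasted against the contralateral homologous parcels; exporters for
   BrainNet Viewer (`.node`/`.edge`) and circular connectogram tables.

Because the underlying patient scans are not publicly deposited, the
package ships a synthetic-cohort generator with known ground truth: a
modular (block) covariance with unit diagonal, AR(1)-smoothed Gaussian
signals plus white noise, and a lesion model that attenuates the flagged
parcels' covariance at all anatomical ranges.

## Worked example

```r
library(lesionnet)

atlas <- default_atlas()                       # 116 parcels
gt <- make_ground_truth(atlas, n_modules = 4,
                        within_r = 0.5, between_r = 0.1, seed = 1)
lesion <- atlas$id[atlas$hemisphere == "r" & atlas$lobe == "parietal"]
gt_lesioned <- apply_lesion(gt, lesion, attenuation = 0.3)
cohort <- simulate_cohort(gt_lesioned, n_subjects = 5, n_volumes = 269,
                          tr_seconds = 2.42, seed = 1)

config <- pipeline_config(scales = 1:3, n_nulls = 50,
                          attack_repeats = 20, null_realizations = 5,
                          seed = 1)
result <- run_pipeline(cohort, config = config, lesion_parcels = lesion)
result
```

```
<pipeline_result> scales analysed: 1, 2, 3; admissible: 1, 2, 3; analysis scale: 3
<network_summary> L_net = 1.78, C_net = 0.51, lambda = 0.77, gamma = 4.79, delta = 6.22 (50 rewired nulls)
degree distribution best fit: truncated_power_law
<lesion_report> 5 at-risk parcels, 0 at-risk edges (contralateral: 49)
                  at_risk contralateral
intra_lobar             0             5
intra_hemispheric       0            22
inter_hemispheric       0            22
```

Reading this output: all three analysed wavelet scales supported a
551-edge network at the required mean degree; the scale with the highest
small-world index was carried forward (δ = 6.22 — strongly exaggerated
relative to real cortex because the synthetic ground truth is perfectly
modular; see the methods vignette). The degree distribution is best fit
by an exponentially truncated power law, and the simulated right-parietal
lesion (connectivity attenuated to 0.3 of its healthy value) leaves its
five parcels with **0** retained edges against **49** for their left-
hemisphere homologs, split into intra-lobar, intra-hemispheric and
inter-hemispheric connections — the "connections-at-risk" contrast.

```r
result$robustness
```

```
<null_comparison> targeted-attack giant-component AUC:
  brain      0.473
  random     0.394
  scale_free 0.343
```

Smaller area under the attack curve means faster degradation: the
scale-free null family collapses fastest under degree-targeted attack,
while random error (not shown) affects all families about equally.

Artifacts (correlation matrices, adjacency/edge lists, metrics tables,
degree-fit report, attack curves, lesion report, BrainNet and circular
exports) are written by passing `output_dir =` to `run_pipeline()`.

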