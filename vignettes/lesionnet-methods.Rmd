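---
title: "Wavelet connectomes and lesion network analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet connectomes and lesion network analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionnet)
```

This vignette documents the statistical model behind `lesionnet`, the
conventions it adopts where the field admits several, and what the
synthetic validation data can and cannot establish about behaviour on real
scans.

## The analysis model

A functional connectome is built in four stages.

**Wavelet correlation.** Parcel-mean BOLD series are decomposed with the
maximal overlap discrete wavelet transform (MODWT). Unlike the decimated
DWT, the MODWT keeps one coefficient per time point per scale, is
translation-invariant, and conserves energy, which makes per-scale
correlation estimates well defined. Scale $j$ isolates the dyadic band
$[f_N/2^j,\, f_N/2^{j-1}]$ with $f_N = 1/(2\,\mathrm{TR})$; functional
connectivity is the Pearson correlation $r_{ij}$ between two parcels'
detail coefficients at a scale, computed over non-boundary coefficients
only. At scale $j$ the equivalent filter spans $(2^j-1)(L-1)+1$ points
($L = 8$ for the default filter), so a $T$-volume series yields
$n_\mathrm{usable} = T - (2^j-1)(L-1)$ coefficients; with $T = 263$ after
discard this ranges from 256 at scale 1 to 46 at scale 5, which is why low
frequency scales have markedly weaker statistical support.

**Group averaging.** $r_{ij}$ is averaged edgewise across subjects within
a scale. Significance for the averaged matrix conservatively reuses the
single-subject effective degrees of freedom
($\min_s n_\mathrm{usable} - 2$); no autocorrelation correction beyond the
boundary exclusion is applied.

**Fixed-degree thresholding with an FDR veto.** The binary network keeps
the $m = \mathrm{round}(n \ln n)$ strongest correlations, fixing the mean
degree at $k_\mathrm{net} = 2\ln n$ — for $n = 116$ parcels, $m = 551$
edges and $k_\mathrm{net} \approx 9.5$, about 8 % of the 6670 possible
edges. This density is the customary minimum for estimating small-world
indices. The logarithm is the natural one: only $\ln$ reproduces both the
9.5 mean degree and the 551-edge count, and the edge budget is
$n \cdot k_\mathrm{net}/2$ because each undirected edge contributes two
degree endpoints. A scale is *admissible* only if every retained edge also
survives Benjamini–Hochberg FDR control at $\alpha = 0.05$ across the
$\binom{n}{2}$ tests; otherwise the scale is reported with the maximal
achievable significant edge count and excluded. Rank-$m$ ties are broken
by larger $r$, then lexicographic parcel order, so thresholding is
deterministic.

**Graph characterisation.** Nodal degree, clustering (triangles over
$k(k-1)/2$), mean shortest-path length to reachable nodes, global
efficiency, and information centrality. Small-world indices normalise
$C_\mathrm{net}$ (mean clustering over degree-$\ge 2$ nodes) and
$L_\mathrm{net}$ (mean nodal path length over the giant component) by the
means of a Maslov–Sneppen ensemble: degree-preserving edge rewiring with
$10m$ swap attempts per realization, default 100 realizations, seeded.
$\delta = \gamma/\lambda > 1$ indicates small-world topology.

## Conventions for disconnected graphs

Sparse thresholded networks contain isolated and degree-1 nodes, and every
global measure needs a convention for them:

* clustering is undefined below degree 2 and reported with the sentinel
  $-1$; path length of an isolated node likewise $-1$;
* global efficiency sums $1/d$ over ordered *reachable* pairs and divides
  by $n(n-1)$ with $n$ **fixed at the intact network's size**. Under this
  fixed-denominator convention removing an isolated node changes nothing,
  so its information centrality is exactly $0.00$ — the only convention
  consistent with tabulating degree-0 parcels as $(-1, -1, 0)$;
* $L_\mathrm{net}$ is averaged over the giant component only and
  $C_\mathrm{net}$ over degree-$\ge 2$ nodes, since including sentinel
  values would corrupt the group means.

## Degree-distribution model selection

Three discrete models are fitted to the degrees $k \ge k_\mathrm{min} = 1$
(degree-0 nodes are excluded; a power law has no mass at 0):
exponential $f(k) = e^{-k/\kappa}$, power law $f(k) = k^{-\alpha}$, and
exponentially truncated power law $f(k) = k^{\alpha-1} e^{-k/k_c}$, each
normalised over $k_\mathrm{min} \ldots 10\,k_\mathrm{max}$. Fitting is
maximum likelihood (bounded quasi-Newton, five seeded multistarts) rather
than least squares on the cumulative distribution, because a likelihood is
required for a well-defined AIC. The truncated model's exponent is left
unconstrained in sign so that the model properly nests both one-parameter
alternatives ($\alpha = 1$ recovers the exponential; $k_c \to \infty$ a
power law).

Selection uses AIC with the conventional parsimony rule: all models within
2 AIC units of the minimum are treated as equivalently supported and the
most parsimonious of that set is chosen (`delta_equiv = 2`;
setting it to 0 restores strict minimal-AIC). The rule matters because the
truncated model nests the other two: under a true one-parameter model the
nested likelihood-ratio gain is $\approx \tfrac12\chi^2_1$, so strict
minimal-AIC would spuriously prefer the two-parameter model in roughly a
sixth of datasets no matter how much data is available. With the 2-unit
band, simulation at 5,000 draws recovers the generating family in ≥95 % of
replicates for all three families, while genuinely truncated data still
select the truncated model essentially always — including the majority of
degree sequences from simulated 116-node, 551-edge graphs.

## Robustness simulation

Attack curves remove nodes one at a time (grid step $1/n$) and track the
giant component and global efficiency relative to the intact network,
keeping the intact $n$ in the efficiency denominator throughout so values
are comparable across removal stages. Targeted attack uses the *static*
descending-degree ranking of the intact network (ties by parcel id):
recomputing ranks after each removal is a published variant, but the
static ranking is the convention of the robustness literature this
analysis follows and makes curves deterministic. Random error averages
over seeded random orders (default 100).

Null families for comparison are (a) degree-preserving rewirings of the
empirical network and (b) scale-free graphs built from a power-law degree
sequence via the configuration model, with the exponent calibrated so the
expected mean degree matches $2m/n$ and the edge count then repaired by
random edge addition/removal. A preferential-attachment construction was
rejected: its minimum degree is $\approx m/n$, which removes precisely the
low-degree periphery whose detachment drives vulnerability, making it
anomalously robust to targeted attack. Note that targeted attack is not
pointwise-dominant over random error: on a densely connected graph the
early hub removals leave the giant component complete while a random
removal occasionally detaches a leaf, so the targeted curve can sit one
grid step above the random mean; dominance holds for the integrated curve
(area under the curve), and that is what the tests assert.

## Lesion model and connections-at-risk

A lesion is a set of tumour-adjacent parcel ids — an input, not something
inferred from imaging. In the generator, lesioning multiplies the flagged
parcels' off-diagonal covariance by an attenuation factor in $[0,1]$
(diagonal kept at 1), which reduces their connectivity at intra-lobar,
intra-hemispheric and inter-hemispheric range simultaneously; the
operation is a congruence transform plus a positive diagonal update, so
positive semidefiniteness is preserved by construction. The
connections-at-risk report enumerates retained edges incident to the
lesion set, classifies each edge from the atlas labels (same lobe and
hemisphere → intra-lobar; same hemisphere → intra-hemispheric; otherwise
inter-hemispheric, with midline vermis parcels counting as a third
"hemisphere"), and repeats the enumeration on the contralateral homolog
parcels as the within-subject control. Homolog pairing comes from the
atlas table, not from coordinates.

## The synthetic cohort: what it emulates and what it does not

`make_ground_truth()` builds a block covariance — parcels partitioned into
`n_modules` contiguous communities (atlas-ordered, so left/right homologs
co-habit a module), `within_r` inside and `between_r` across modules, unit
diagonal, clipped to the nearest positive-semidefinite matrix if needed.
`simulate_cohort()` draws zero-mean Gaussian series from it, applies AR(1)
temporal smoothing (default coefficient 0.3, rescaled to unit variance) so
the spectrum is 1/f-like and wavelet scales carry unequal power, and adds
white measurement noise. Defaults mirror the study geometry: 5 subjects,
269 volumes, TR 2.42 s, 15 s initial discard (6 volumes). The default
correlation levels (`within_r = 0.5`, `between_r = 0.1`,
`noise_sd = 1`) were chosen as representative of wavelet-scale BOLD
correlations after noise attenuates observed within-module correlations to
roughly 0.25; they are a modelling choice, not an estimate from the
(undeposited) empirical data.

Limitations to keep in mind when reading test results:

* A block covariance is *perfectly* modular. Thresholded networks
  therefore show exaggerated clustering (small-world $\delta$ well above
  the ≈1.2–1.7 reported for real cortex) and can fragment into
  module-sized components, because between-module correlations rarely
  reach the retention threshold. Real cortex keeps a spanning giant
  component. Passing tests demonstrate that the pipeline's inferences
  track the planted structure, not that synthetic $\delta$ values match
  empirical magnitudes.
* The AR(1) spectrum is a stand-in for the post-denoising BOLD spectrum,
  which the study does not characterise; all wavelet scales share the same
  expected correlation, so scale exclusion in the synthetic world is
  driven purely by the shrinking effective sample size at deeper scales.
* No hemodynamic response, motion, or physiological artefact is
  simulated, and no volumetric data exist — parcel series are generated
  directly.

## Numerical choices

* MODWT boundary: reflection (series extended by its time-reverse before
  circular filtering), the default of the wavelet tooling historically
  used for this analysis; the `"periodic"` option treats the series as
  circular and conserves energy to machine precision, which the test
  suite exploits. Boundary-affected coefficients are excluded from
  correlations either way.
* Effective df for the correlation t-test: $n_\mathrm{usable} - 2$. This
  ignores residual autocorrelation within a scale and is therefore
  slightly liberal; it is the simplest defensible choice and is applied
  uniformly across scales.
* PSD repair: eigenvalue clipping at zero with diagonal renormalisation —
  the simplest reproducible projection.
* Per-subject seeds are derived as `seed + 7919 * subject_index`, keeping
  all derived seeds well below $2^{31}$ for cohort sizes in practical use.
* The analysis scale, when not specified, is the admissible scale with
  the highest $\delta$ — the same rule the motivating study applied.

## Problem sizes used by the test and acceptance suites

Unit tests validate metrics against brute-force oracles (triangle
enumeration, Floyd–Warshall, union-find) on 100 random graphs of up to 30
nodes, and the statistical properties on 116-parcel cohorts of 5 subjects
× 269 volumes. Null ensembles are scaled to the check at hand (8–50
rewirings in end-to-end tests, 100 by default in the API); family-recovery
simulations use 50 replicates of 5,000 draws. These sizes were chosen so
the whole suite exercises the full study geometry while remaining
comfortable to run repeatedly during development.
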