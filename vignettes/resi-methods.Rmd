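---
title: "Methods: sequential-imaging super-resolution analysis with resikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential-imaging super-resolution analysis with resikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resikit)
```

## The model behind RESI

DNA-PAINT produces, for every target molecule, a cloud of independent
localizations that are to good approximation Gaussian-distributed around
the true position with standard deviation $\sigma_{\mathrm{SMLM}}$ (the
localization precision). If the $K$ localizations of one cloud can be
attributed unambiguously to one molecule, their (weighted) mean estimates
the molecular position with precision

$$\sigma_{\mathrm{RESI}} = \frac{\sigma_{\mathrm{SMLM}}}{\sqrt{K}},$$

i.e. the standard error of the cloud mean. The attribution is the hard
part: at biological densities, clouds of neighbouring molecules overlap.
Sequential imaging solves this by splitting one target species over $n$
orthogonal label sequences imaged in separate rounds, which divides the
effective density per round by $n$ and isolates the clouds. `resikit`
implements the computational side of this workflow: round alignment,
per-round cloud clustering, cloud collapse, precision bookkeeping, the
design calculators that say how many rounds are needed, and the
nearest-neighbour statistics used downstream.

## Clustering of localization clouds

`cluster_locs()` implements a density-peak clusterer. For each
localization the number of neighbours within radius $r$ is counted; a
localization is a *local maximum* when no localization inside its $r$
neighbourhood has a larger count. Every localization within $r$ of a
maximum joins that maximum's cluster (maxima are processed in order of
decreasing count, and localizations are never shared); clusters with at
most `n_min` members are dissolved.

Parameter guidance, with the package defaults:

* `r` (nm): sets the cluster size; about twice the localization
  precision of the round is a good starting point. Too large merges
  neighbouring targets, too small splits one cloud into sub-clusters
  (visible as a spurious nearest-neighbour peak at $2r$).
* `n_min`: the minimum evidence for a real target.
  `suggest_n_min()` estimates it as the antimode of the per-pick count
  histogram when that histogram separates a background mode from a
  single-target mode.
* `r_z` (nm, 3D): axial clustering radius. Axial localization scatter is
  roughly twice the lateral scatter in astigmatic 3D imaging, so
  `r_z = 2 r` is the natural default; the 3D neighbourhood is the
  ellipsoid $\sqrt{dx^2 + dy^2 + (dz \cdot r / r_z)^2} \le r$.

Two temporal filters remove artifacts of non-specific imager sticking:

* *Mean-frame filter*: genuine repetitive blinking is uniform over the
  acquisition, so a cluster's mean frame concentrates near half the
  total frame count. Clusters whose mean frame falls in the first or
  last 20% of frames (`edge_fraction = 0.20`, boundaries rejected
  inclusively) are discarded.
* *Window filter*: the acquisition is divided into `n_windows = 20`
  equal windows (5% of frames each); a cluster with more than
  `window_max_fraction = 0.80` of its localizations inside a single
  window is a temporally compact burst — a sticking event — and is
  discarded. Windows are aligned to the acquisition start.

Tie-breaks are deterministic: a count tie between mutually neighbouring
localizations is resolved in favour of the lowest index, so a flat-topped
cloud still yields exactly one maximum, and the whole assignment is
reproducible regardless of evaluation order. The `n_min` threshold is
strict (a kept cluster has *more than* `n_min` members).

## Collapsing clusters: the weighted mean and its precision

`collapse_clusters()` turns each kept cluster into one super-localization.
With per-localization precisions $\mathrm{lp}_i$ and weights
$w_i = 1/\mathrm{lp}_i^2$,

$$\bar{x}_{\mathrm{wtd}} = \frac{\sum_i w_i x_i}{\sum_i w_i},
\qquad
\mathrm{Var}(x)_{\mathrm{wtd}} = \frac{N}{N-1}
\frac{\sum_i w_i (x_i - \bar{x}_{\mathrm{wtd}})^2}{\sum_i w_i},
\qquad
(s_{\bar{x}})_{\mathrm{wtd}} = \sqrt{\mathrm{Var}(x)_{\mathrm{wtd}} / N}.$$

Under the Gaussian model the inverse-variance weighted mean is the
maximum-likelihood estimator of the cloud centre, hence minimum-variance
among linear unbiased estimators; with equal weights the formulas reduce
to the ordinary mean and Bessel-corrected standard error. The reported
lateral precision is the *average* of the $x$ and $y$ weighted s.e.m.
(not their quadrature sum). The axial coordinate uses an unweighted mean
and its precision is taken as twice the lateral precision, consistent
with the twofold axial spread; no per-localization axial precision is
stored. Rendered images (`render_resi()`) splat each record as a
unit-mass Gaussian with s.d. equal to its own precision, truncated at
5 s.d. (mass deficit below $10^{-5}$).

## Quantifying precision

`insilico_curve()` estimates $\sigma_{\mathrm{RESI}}(K)$ by simulation:
$M$ localizations per site, partitioned into $n = M/K$ *disjoint* random
subsets (disjointness matches the $n = M/K$ subset count; sampling with
replacement would correlate subsets), each averaged, and the spread of
the subset means summarized by the scalar metric
$\sigma = \sqrt{\tfrac{1}{2}\,\mathrm{tr}\,\mathrm{cov}(x, y)}$
(`scalar_spread()`). `resample_cluster()` applies the same resampling to
an experimental cluster, requiring $M \ge 10K$ so that at least ten
subset means support the spread estimate, and extrapolates the final
precision of the all-$M$ collapse as $\hat\sigma_{\mathrm{SMLM}}/\sqrt{M}$.
Error bars across binding sites are reported as one standard deviation.

## Design calculators

With $n$ orthogonal sequences at equal concentration each molecule is
labelled with sequence $i$ with probability $1/n$. The probability that
a pair carries distinct sequences is $1 - 1/n$ (75% at $n = 4$), and for
$m$ co-located molecules the fully-distinct probability is
$n!/((n-m)!\,n^m)$. For targets distributed with complete spatial
randomness (CSR) at density $\rho$, the fraction unresolved in one round
is the CSR first-nearest-neighbour CDF evaluated at the resolvability
distance $d$:

$$F = 1 - e^{-(\rho/n)\,\pi d^2}, \qquad d = 4\,\sigma_{\mathrm{SMLM}}$$

by default — a deliberately stricter criterion than the FWHM-based
$2.35\,\sigma$. Acquisition time follows from the binding kinetics: with
on-rate $k_{\mathrm{on}}$, imager concentration $c$, mean bright time
$\tau_b$ and exposure $t_e$, collecting $n_{\mathrm{loc}}$ localizations
takes on average $t = t_e\,n_{\mathrm{loc}} / (\tau_b\,k_{\mathrm{on}}\,c)$,
and $n_{\mathrm{loc}} = \lceil (\sigma_{\mathrm{SMLM}} /
\sigma_{\mathrm{RESI}})^2 \rceil$ — rounded up, since localizations come
in integers.

## The monomer/dimer mixture model and its fit

For membrane receptors the package models the observed point pattern as
a superposition of CSR monomers and CSR-centred dimers. A dimer emits
two molecules separated by exactly $D$ nm along a uniformly random
orientation; every molecule position is then perturbed by an isotropic
Gaussian of s.d. $\sigma_{\mathrm{label}}$ (labelling plus residual
localization error) and molecules are thinned independently with the
labelling efficiency. Two modelling decisions deserve note:

* The intra-dimer distance is drawn *deterministically* equal to $D$;
  the position uncertainty creates the spread. The expected inter-point
  distance consequently exceeds $D$ slightly (a Rician-type effect).
  Because the fitter simulates with the identical generative code, fit
  and simulation are self-consistent and the effect cancels in
  parameter recovery.
* "Dimer density" counts *pairs* per µm², each contributing two
  molecules. The fit is parameterized by the percentage of molecules
  belonging to dimers, so that observed density =
  ground-truth molecule density × labelling efficiency holds exactly
  and the monomer percentage is its complement.

`fit_dimer_model()` minimizes the sum of squared differences between the
first-nearest-neighbour histograms (1 nm bins over 0–100 nm by default;
1 nm resolves the dimer peak while keeping per-bin counts stable at the
~21,000-point scale this analysis targets; the width is configurable) of
the data and of patterns simulated at candidate parameters, with the
simulation window sized so the simulated density matches the observed
density. The search is a coarse 11×11×11 grid over $D = 1$–20 nm,
$\sigma_{\mathrm{label}} = 1$–20 nm, dimer fraction 0–100%, followed by a
fine stage over a box of one coarse step around the coarse optimum: a
7×7×7 grid is evaluated and a quadratic response surface is fitted to
the evaluated sum-of-squares; the surface minimizer (used when the
fitted Hessian is positive definite and the minimizer stays inside the
box, otherwise the best evaluated grid point) is reported. The surface
fit averages simulation noise over all fine-grid evaluations and frees
the estimate from the grid spacing — on a stochastic objective this is
markedly more stable than a simplex search, while remaining an
"iterative least-squares over a reduced parameter space". Two further
variance-reduction devices: all evaluations of a stage share common
random-number seeds, and fine-stage simulations use a window enlarged
fourfold in area (`sim_area_factor`), which shrinks the Monte-Carlo
noise of the simulated histogram without altering the model.

`fit_uncertainty()` quantifies parameter uncertainty by parametric
refitting: $M$ datasets are simulated at the fitted optimum with the
same number of molecules as the data, each is fine-fitted, and the
standard deviation of each parameter across refits is its uncertainty
($M = 100$ by default; fewer than 10 refits is flagged as indicative
only).

All nearest-neighbour computations use exact cell-grid searches
(compiled), and CSR/mixture patterns are generated in a window enlarged
by a 100 nm guard band and evaluated only in the inner window, which
removes the edge deflation of nearest-neighbour distances; the guard
points still serve as candidate neighbours.

## What the synthetic generator does and does not emulate

`make_layout()`, `assign_channels()` and `sample_localizations()`
reproduce the statistical structure the analyses rely on: Gaussian
localization scatter with the stated $\sigma$, twofold axial spread,
uniform or kinetic frame statistics, stochastic channel assignment with
probability $1/n$, and sticking artifacts injected as temporally
compact clusters at random off-site positions. They deliberately do not
model photophysics (photon budgets, PSF shape, astigmatism
calibration), stage drift, camera noise, or sequence-specific binding
kinetics — those belong to the upstream raw-data pipeline. Passing
tests therefore demonstrate the correctness of the clustering,
collapse, design and fitting mathematics under the Gaussian model, not
robustness to upstream artifacts that real acquisitions may contain.

## Problem sizes and reproducibility

The simulation scales used throughout the package's tests and in
`scripts/acceptance.R` were chosen as the smallest sizes at which each
statistical claim is decisive: precision curves use $M = 5120$
localizations per site over eight sites; the two-site origami experiment
uses $K = 381$ localizations per site over 50 replicates; the
ring-complex recovery uses eight 32-site complexes; the mixture fit uses
~21,000 detectable molecules (the scale of a whole-cell receptor
dataset) with ten independent datasets and reduced refit replication
($M = 8$). Every stochastic routine accepts a seed, and all generators
are bit-reproducible given (seed, parameters).

## Known limitations

* Clusters are disks/ellipsoids by construction; strongly anisotropic
  clouds (e.g. from residual drift) are split or truncated rather than
  modelled.
* The window filter is aligned to the acquisition start, so a sticking
  event straddling a window boundary can evade the 80% rule; the
  mean-frame filter catches most such cases near the edges of the
  acquisition.
* `fit_dimer_model()` fits first-order neighbour distances only; mixed
  higher-order structure (chains, hexamers) is out of its scope, though
  `knn_distances()` exposes orders 1–4 for CSR-consistency checks.
* The HDF5 reader/writer targets the single-dataset Picasso dialect
  (record array `locs` plus YAML sidecar), not the full Picasso schema,
  and delegates the container I/O to a bundled Python helper built on
  h5py, the dialect's canonical implementation.
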