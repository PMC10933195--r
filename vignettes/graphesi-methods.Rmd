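---
title: "Spatial graph filters for EEG/MEG source imaging: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial graph filters for EEG/MEG source imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphesi)
```

## The inverse problem

EEG/MEG source imaging reconstructs cortical activity $S \in \mathbb{R}^{N
\times T}$ from sensor data $Y = K S + E$, where $K \in \mathbb{R}^{C \times
N}$ is the leadfield and $C \ll N$ (a 128-channel montage against ~2000
cortical sources). The problem is ill-posed; every estimator in this package
solves

$$\hat S = \arg\min_S \tfrac12 \lVert Y - K S \rVert_F^2 + \lambda R(S)$$

with a different regularizer: the ridge penalty (MNE) and its standardized
variants (sLORETA, dSPM), the entrywise $\ell_1$ penalty (MCE), and the
row-wise $\ell_{2,1}$ mixed norm (MxNE-L21).

## The spatial graph Fourier basis

The cortical mesh defines an undirected graph $G = \{\mathcal{V}, A\}$:
vertices are source locations, edges are triangle edges (unit weights by
default; inverse-distance weights optional). With degree matrix $D$ the
Laplacian is $L = D - A$, and its eigenvectors $U = [u_1, \dots, u_N]$ form
the graph Fourier basis. We order them not by eigenvalue but by
**normalized graph frequency**,

$$f_G(u_i) = \frac{f_s(u_i)}{\operatorname{Tr}(L)}, \qquad
  f_s(u_i) = \tfrac12 \sum_m \sum_{n \in \mathcal{N}(m)}
  \mathbb{1}\left[u_i(m)\, u_i(n) < 0\right],$$

the number of sign flips across neighbor pairs (order-$k$ neighborhoods,
$k = 1$ by default) scaled by the Laplacian trace. The strict inequality
means an exactly-zero component never contributes a flip; components within
`1e-9` (relative) of zero are treated as zeros so that rounding error in a
stored eigenvector cannot fabricate a flip. NGF correlates strongly with the
eigenvalue order (Spearman > 0.98 on our source spaces) but is the
directly interpretable quantity: spatial oscillation per unit of graph
weight.

Keeping the $P$ eigenvectors with the smallest NGF (ties broken by
eigenvalue, then index) yields the low band $\tilde U \in \mathbb{R}^{N
\times P}$. Solving the inverse problem in that subspace — $\tilde K = K
\tilde U$, penalize $\tilde S^\ast$, back-project $\hat S_{GFT} = \tilde U
\hat S^\ast$ — restricts estimates to smooth, spatially extended patterns
and discards high-spatial-frequency noise. Note the projected sparse
penalties act on *spectral coefficients*, not on sources: GFT-MCE is a
genuinely different estimator from MCE, not a change of variables (the
$\ell_1$ norm is not rotation-invariant). Only the quadratic (MNE) solution
is exactly invariant under the full-basis projection, and the test suite
pins that down.

### Choosing P

The full-scale benchmark keeps $P = \max(C, \lceil 0.05 N \rceil)$ — with
128 channels and ~2200 sources, $P = 128$. Rationale: the reduced problem
should not be *more* underdetermined than the original, and ~5% of the
spectrum comfortably spans three-ring patches on meshes at this resolution.
A threshold selector (`ngf_threshold`) is also provided; $P(\tau)$ is
nondecreasing in $\tau$.

## Solvers and numerical choices

* **MNE**: $\hat S = K^T (K K^T + \lambda I)^{-1} Y$ via a Cholesky solve,
  never an explicit inverse.
* **sLORETA / dSPM**: the printed forms apply full-matrix $(-1/2)$ powers of
  the resolution matrix $R = K^T(KK^T+\lambda I)^{-1} K$ (sLORETA) or of
  $M M^T$, $M = K^T(KK^T+\lambda I)^{-1}$ (dSPM). We evaluate them through
  the economy SVD $K = U_s \Sigma V_s^T$: on the signal subspace the
  sLORETA map collapses to $V_s\, (\Sigma^2 + \lambda)^{-1/2} U_s^T$ and
  the dSPM map to $V_s U_s^T$ exactly, which is algebraically identical to
  the eigendecomposition-with-floor route on the components that carry
  signal, and avoids amplifying rounding noise in the numerical null space.
  Components below `1e-10` (relative singular value) are treated as rank
  deficiency. A `standardization = "diagonal"` switch implements the
  per-source variant used by several ecosystem implementations; the
  full-matrix form is the default because it is the printed equation.
* **MCE / MxNE-L21**: FISTA with step $1/\lVert K \rVert_2^2$ (power
  iteration, 1% inflation), adaptive restart plus a monotone (MFISTA)
  safeguard, stopping when the *relative* objective decrease stays below
  `tol` (default `1e-6`) for three consecutive iterations, capped at
  `max_iter = 1000`. The relative criterion matters: leadfield units are
  arbitrary, so an absolute threshold silently stops the solver at a dense,
  barely-thresholded iterate. Hitting `max_iter` sets a flag on the
  estimate instead of raising an error, so Monte-Carlo loops keep running.
* **$\lambda$ defaults** (always explicit arguments; these are only the
  benchmark defaults): closed-form solvers use the classical heuristic
  $\lambda = \operatorname{tr}(K K^T) / (C \cdot \text{SNR})$ with SNR on
  the linear scale; sparse solvers use $\lambda = 0.1\, \lambda_{\max}$,
  where $\lambda_{\max}$ is the smallest $\lambda$ with an all-zero
  solution. The source publication does not report its $\lambda$ values;
  these choices were fixed before the benchmarks were run and not revisited.

## The synthetic world

No MRI/BEM head model ships with the package; the forward model is the
classical three-concentric-spheres conductor.

* **Geometry**: brain/skull/scalp shells at 80/85/92 mm with
  conductivities 0.33/0.0042/0.33 S/m (the textbook Rush–Driscoll 1:80
  skull ratio). Sensors: 128 points on the upper 85% of the scalp sphere
  (a Fibonacci lattice; EEG caps do not cover the underside of the head).
* **Sources**: a frequency-15 geodesic sphere at 65 mm eccentricity split
  at the midsagittal plane into two disjoint hemispherical caps — 2192
  sources, the closest attainable geodesic count to the reference
  2052-source (1026 per hemisphere) cortical space. Dipoles are radial,
  fixed-orientation. Per harmonic degree the layered-sphere transfer
  coefficient is obtained by solving the 5-equation boundary system
  (potential and radial current continuity, insulating scalp) — setting all
  conductivities equal reproduces the homogeneous-sphere closed form
  $(2n+1)/n$ to machine precision, which the tests assert.
* **Patch sources**: a seed vertex at amplitude 1.0 and its hop-$r$ rings
  at 80%, 60%, 40% for $r = 1, 2, 3$; the localization waveform is a
  unit-peak Gaussian-windowed sinusoid (T = 100 samples at 100 Hz — any
  smooth course works, the extent metrics integrate energy over time).
* **Sensor noise**: i.i.d. Gaussian, scaled so the realized power ratio
  matches the target SNR exactly (the realization is rescaled, so
  "empirical SNR within 0.1 dB" holds by construction, not on average).
* **Causal experiment**: two non-overlapping level-2 patches driven by a
  stationary AR(1) with a random $2 \times 2$ transition matrix rescaled to
  spectral radius 0.9; innovations are unit Gaussian; 100-sample burn-in;
  T = 500 at 100 Hz. Sensor noise is added first and the zero-phase
  third-order Butterworth band-pass (0.1–40 Hz) is applied last, in that
  printed order. **Design choice**: the AR source courses themselves are
  band-limited with the same zero-phase filter before projection. A raw
  stable AR draw frequently has transition eigenvalues with phase near
  $\pi$ and oscillates near the Nyquist rate; no band-limited measurement
  retains that energy, so under the raw-course reading the correlation
  metric measures the filter, not the estimator (even an oracle inverse
  cannot exceed ~0.55 on average). Band-limiting the ground truth makes the
  simulated brain signal live in the analysis band, as in the
  connectivity-benchmark family this design emulates.

### What the generator does not emulate

Real data have correlated sensor noise, eye/muscle artifacts, folded
cortical geometry with depth- and orientation-dependent gain, and
head-model error. The spherical world is symmetric and every source is
equally visible; sparse solvers therefore localize *better* here than on a
real BEM leadfield (where MCE is known to fragment into spikes near
chance-level extent overlap). A green statistical test on this world
establishes internal correctness of the estimators and the orderings that
survive the substitution (GFT-L21 above L21, GFT smoothing advantages), not
absolute agreement with BEM-based numbers.

## Evaluation conventions

* **Localization error**: Euclidean distance from the true patch center to
  the vertex of maximal time-integrated power (an energy-weighted centroid
  option exists). An all-zero estimate gets the maximal possible distance,
  flagged, with a warning — an arbitrary argmax would be meaningless.
* **Extent AUC**: Mann–Whitney rank statistic of per-source energies
  against the binary active set, ties averaged; equivalent to a full
  threshold sweep and invariant to monotone transforms.
* **Time-course correlation**: Pearson correlation between each patch's
  true course and the energy-weighted average of the estimate over that
  patch's true support, averaged over patches; polarity is not rectified.
* **Paired t tests** with the printed star ladder `* p<0.5`, `** p<0.05`,
  `*** p<0.005`. The 0.5 threshold is reproduced as printed (it is almost
  certainly a typo for a conventional ladder, but it is what the figure
  legend states); a Bonferroni-corrected column is emitted alongside.

## Known limitations

* Constant source eccentricity (no sulcal depth variation) — see above;
  this is the main driver of the remaining gap to the printed MCE numbers.
* Fixed radial orientations; no free-orientation (3-component) dipoles.
* The NGF band split into L/M/H thirds is a labeling convenience; only the
  low band is used by the solvers.
* FISTA is the only sparse solver; no coordinate descent or active-set
  path.
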