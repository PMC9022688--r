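---
title: "Models and methods behind mconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mconn)
```

## Overview

`mconn` implements a structural and functional connectomics pipeline for the
mouse brain of the kind used to study vascular cognitive impairment: group
spatial ICA of resting-state fMRI with automated noise screening,
hierarchical clustering of components into resting-state networks (RSNs),
seed-based default-mode-network mapping, edge-wise group comparison with FDR
control, diffusion-tensor fitting and fractional anisotropy (FA),
probabilistic streamline tractography with log-weighted streamline-count
connectomes, and graph-theory characterization under proportional
thresholding.

Because no suitable public mouse dataset accompanies this problem setting,
the package is built around *synthetic phantoms with known ground truth*.
The phantom generators are first-class, tested code: they define the exact
statistical structure the analysis stages assume, which lets every stage be
validated quantitatively (recovery rates, power, error control) rather than
just visually.

## The functional phantom

A subject's 4D series on an $X \times Y \times Z$ grid is

$$ y(v, t) \;=\; \sum_k m_k(v)\, s_k(t) \; + \; \varepsilon(v,t), \qquad
   \varepsilon \sim N(0, \sigma^2), $$

with Gaussian-profile spherical maps $m_k$ (sd = radius/2, truncated at
twice the radius, restricted to an ellipsoidal brain mask at 90% of the grid
extent) and cluster-structured time courses

$$ s_k(t) \;=\; \mathrm{sign}_k \left( \sqrt{w}\, f_{c(k)}(t)
   + \sqrt{1-w}\,\eta_k(t) \right). $$

The latent cluster factors $f_c$ are built by mixing i.i.d. standard normal
series with the Cholesky factor of a target factor correlation matrix, so
requested inter-cluster correlations (for example an anticorrelated pair at
$-0.5$, the analogue of the sensorimotor–visual vs limbic anticorrelation
seen in mouse resting-state data) hold in expectation, and the expected
within-cluster correlation of true time courses equals exactly $w$.

Two details deserve emphasis:

* **Temporal smoothing.** Signal series ($f_c$ and $\eta_k$) are low-pass
  filtered with a Gaussian kernel (sd 3 TR) *before* standardization and
  mixing. Real BOLD fluctuations are dominated by frequencies below
  ~0.1 Hz, and the automated noise classifier uses exactly that property;
  unsmoothed (white) signal time courses would be indistinguishable from
  scanner noise in the frequency domain. Because the same marginal filter is
  applied to every latent series prior to mixing, all target correlations
  (and hence the $w$ calibration) are preserved exactly. The price is a
  reduced effective number of temporal degrees of freedom (roughly $T/10$ at
  the default kernel), which the power analyses below inherit.
* **Noise components.** Optional artifact components live on the outermost
  one-voxel shell of the brain mask and have temporally *white* time
  courses — the two signatures (edge-concentrated support, high-frequency
  power) that the automated classifier tests.

The reference phantom (`default_rsn_spec()`) fixes the study conditions used
throughout the tests: 4 clusters × 3 components on a 24×24×12 grid,
$w = 0.6$, one anticorrelated cluster pair at $-0.5$, $T = 300$ at TR = 1 s,
unit component amplitude with noise sd 0.2 (peak SNR ≈ 5), and 3 edge noise
components. A two-group cohort differs only in distributional parameters —
the "hypoperfused" group lowers $w$ to 0.3 in cluster 1 — while sharing
component geometry, so group differences are purely in connectivity
strength, as in the disease model being emulated.

What the phantom deliberately does *not* model: hemodynamic response
convolution, motion and physiological confounds, spatial autocorrelation of
scanner noise, and between-subject anatomical variability. Passing tests
therefore demonstrate the correctness and calibration of the *analysis*
under its own assumptions, not robustness to those real-data complications.

## Group spatial ICA

Subjects are temporally concatenated after per-voxel, within-subject
demeaning and variance normalization (zero-variance voxels are dropped and
reported). The concatenated matrix is reduced by SVD to $k$ components
(user-set; default retains 95% of variance) and unmixed with a symmetric
fixed-point ICA using the logcosh nonlinearity on the *voxel* dimension, so
sources are spatial maps — the convention of MELODIC-style group ICA. The
whitened basis is centered over voxels before unmixing (the fixed-point
update assumes zero-mean variables), which can cost at most a rank-one
direction of the PCA subspace; the subspace-variance test allows for exactly
that. Maps are normalized to unit Euclidean norm with the peak voxel made
positive, making output deterministic given the seed. Per-subject time
courses are recovered by least-squares regression of each subject's data on
the group maps (the first dual-regression stage); these define the
subject-level edge correlations used downstream. Non-convergence after
`max_iter` iterations raises an error carrying the iteration count.

One consequence of variance normalization worth knowing when interpreting
recovery tests: a planted Gaussian-profile map of amplitude $a_v$ appears in
the standardized data attenuated to $a_v / \sqrt{a_v^2 + \sigma^2}$. The
recovery tests therefore compare recovered maps to the truth on that
standardized scale, which is the scale the algorithm actually observes.

### Automated noise screening

The study setting this package emulates classified noise components
manually. `classify_noise()` automates the decision with two configurable
criteria, either of which flags a component:

* spatial: more than 50% of supra-threshold voxels ($|z| > 2.3$ of the
  z-scored map) lie on the outermost mask shell;
* temporal: more than 50% of time-course spectral power lies above 0.1 Hz
  (averaged over subjects).

Components with no supra-threshold voxels are marked *indeterminate*, never
noise. The thresholds are defaults, not claims about reproducing any manual
classification on real data.

## Functional connectome, clustering, group comparison

Component-pair Pearson correlations are computed per subject over time and
variance-stabilized with the Fisher transform $z = \operatorname{atanh}(r)$
(values with $|r| \ge 1 - 10^{-7}$ are clipped with a warning). Group-level
correlation matrices are obtained by averaging subject $z$ matrices.

RSNs are formed by agglomerative hierarchical clustering with **average
linkage** on the distance $d_{ij} = 1 - r_{ij}$ using the *signed*
correlation, so anticorrelated component pairs are maximally distant — this
is what separates an anticorrelated limbic-type cluster from a
sensorimotor-type cluster. The dendrogram is cut at a user-chosen $k$
(4 in the emulated study; no automatic cut selection is attempted since no
defensible criterion was available), and cluster ids are ordered by
descending size with ties broken by smallest member id, making labels
deterministic and permutation-equivariant.

Edge-wise group differences are tested per unique component pair on the
subjects' $z$ values with Welch's $t$ (default) or the Mann–Whitney $U$ test
(normal approximation with tie correction), two-sided, followed by
Benjamini–Hochberg FDR over the $n(n-1)/2$ upper-triangle edges only. The
choice between $t$ and $U$ is an explicit flag rather than an automatic
normality gate, keeping the analysis reproducible.

Seed-based maps average the time courses of the voxels in a seed region,
correlate every in-mask voxel against that reference, and Fisher-transform
the result; with `concatenate = TRUE` the map is computed once on the
temporally concatenated group matrix (the variant that produces a
group-level default-mode pattern), otherwise per subject with z-averaging.

## The diffusion phantom and tensor model

The diffusion phantom defines a ground-truth tensor per voxel: inside a
geometric bundle (a straight cylinder or a quarter circular arc joining two
endpoints) the tensor is axially symmetric with principal axis along the
local bundle tangent, $D = \lambda_\perp I + (\lambda_\parallel -
\lambda_\perp)\, t t^\top$; elsewhere it is isotropic. Defaults use
white-matter-like diffusivities ($\lambda_\parallel = 1.7\times10^{-3}$,
$\lambda_\perp = 0.3\times10^{-3}$ mm²/s, FA ≈ 0.78) over a gray-matter-like
background ($0.7\times10^{-3}$ mm²/s), 12 Fibonacci-hemisphere gradient
directions at $b = 1000$ s/mm² plus two $b=0$ volumes. Signals follow
$S = S_0 \exp(-b\, g^\top D g)$ with Rician noise implemented as the
magnitude of the signal plus complex Gaussian noise ($\sigma = 0$ returns
the noiseless signal exactly).

`fit_tensor()` solves the log-linearized model by ordinary least squares in
the 7 unknowns per voxel. Nonpositive samples are dropped per voxel; voxels
with fewer than 7 usable measurements are marked invalid; negative
eigenvalues are clamped to zero with a per-volume count reported. On
noiseless phantom data the fit reproduces the ground-truth tensor elements
to better than $10^{-6}$ (in practice to machine precision), which is the
round-trip property the test suite asserts.

FA uses the standard normalized eigenvalue-dispersion formula and is defined
as 0 for an all-zero tensor. Group FA comparison is a voxel-wise Welch $t$
with BH-FDR across voxels — deliberately plain voxel-wise testing; TBSS-style
skeleton projection is out of scope.

## Probabilistic tractography and the structural connectome

From every seed voxel, streamlines are propagated in both directions with a
fixed step (default 0.5 voxel). Each step direction is drawn from a von
Mises–Fisher cone (default concentration $\kappa = 50$; the high-confidence
tests use $10^3$) around the principal eigenvector at the current voxel
(nearest-voxel lookup), sign-aligned with the previous direction.
Propagation stops on FA below `fa_stop` (default 0.15), turning angle above
`angle_limit_deg` (default 60°), leaving the grid/mask, or `max_steps`. The
two half-tracks share one initial direction (one negated), so the joined
polyline also honors the angle limit at the junction — a property asserted
per streamline in the tests. Streamline points are kept in world
coordinates; voxel ownership is half-open, $[i, i+1)$ per axis, 0-based.

A streamline contributes to the connectome through the unordered pair of the
*first and last* labeled regions it touches (endpoint convention, stated
explicitly because alternatives — counting all visited regions — exist).
Streamlines touching fewer than two labeled regions are discarded and
tallied. Edge weights are $\ln(1 + \text{count})$: the log transform
compresses the heavy-tailed count distribution and the $+1$ offset keeps
zero-count edges finite.

On the straight-bundle phantom with seeds in the bundle core, essentially
all streamlines reach the far end region at high concentration (the tests
require ≥ 95%). On the quarter-arc phantom the end-to-end rate is lower
(roughly 60% at the default step size — curvature plus nearest-voxel
orientation lookup lets some streamlines exit the outer wall) but still far
above any background false-connection rate, which is the property the tests
assert.

## Graph metrics

Network characterization operates on the *binarized* graph after
proportional thresholding: the top $\lfloor d \cdot n(n-1)/2 \rfloor$ unique
edges by weight are kept (ties broken lexicographically, so the operation is
deterministic), which matches network density across compared groups —
density is a known confounder of graph metrics. For functional matrices the
default keeps the most-positive signed edges; callers who prefer magnitude
thresholding can pass $|z|$ explicitly.

* Global efficiency: mean inverse shortest-path length over ordered node
  pairs, with disconnected pairs contributing 0 (the standard convention,
  not an error).
* Local efficiency of a node: global efficiency of the subgraph induced by
  its neighbours; degree < 2 gives 0.
* Transitivity: $3 \times$ triangles / connected triples, with $0/0 := 0$.
* Degree: adjacency row sums.

All four are implemented directly on the adjacency matrix (matrix-BFS
distances, triangle counting via the adjacency cube) and are verified in the
test suite against two independent references: a naive Floyd–Warshall plus
exhaustive triple-enumeration oracle on 500 random graphs, and `igraph` on
larger graphs.

## Statistics

Welch's $t$ (with Welch–Satterthwaite degrees of freedom) and the
Mann–Whitney $U$ test are the two-sample workhorses; degenerate inputs
(identical constant samples) return $p = 1$ with a flag rather than an
error, since edge-wise scans routinely hit constant edges. All $p$-values
are two-sided. BH-FDR uses the classic step-up rule; its rejection set is
cross-checked against `p.adjust(method = "BH")` in the tests, and its
empirical FDR is verified on 1000 all-null simulations.

## Determinism and numerical choices

Every stochastic operation takes one integer seed; internal per-subject /
per-stage streams are derived by fixed prime offsets (`substream_seed`), and
all RNG use is scoped so library calls never perturb the caller's RNG state.
Identical spec + seed reproduces outputs bit for bit, including written TSV
files (checksummed in the pipeline report). Other numerical conventions:
ICA convergence tolerance $10^{-6}$ on the unmixing update with symmetric
decorrelation; correlation clipping at $1 - 10^{-7}$ before the Fisher
transform; tensor eigenvalues sorted descending with negatives clamped to 0;
FA clamped to $[0,1]$.

## Problem sizes used in testing

The routine test suite and the acceptance script use the reference phantom
sizes above (24×24×12 functional grid with ~2600 mask voxels, $T = 300$,
4-subject group ICA at model order 12; 20×12×8 diffusion grid with 14
volumes), with 20-replicate Monte-Carlo summaries for recovery/power
properties and 200 replicates for null FDR calibration. These sizes were
chosen so each validation property is estimated with usefully small
Monte-Carlo error while the entire suite stays convenient to run
interactively.

## Known limitations

* The phantoms validate calibration and correctness under the generator's
  assumptions; no claim is made about preprocessing robustness on scanner
  data (motion, distortion, registration are out of scope).
* The automated noise classifier is a proxy for expert manual
  classification, with configurable thresholds; it is tuned to the phantom's
  two artifact signatures.
* Model order selection for ICA beyond the 95%-variance default is the
  user's responsibility.
* Tractography uses a single-tensor model with a simplified probabilistic
  sampler; crossing fibers and anatomically constrained tracking are not
  modeled.
* The quarter-arc phantom shows the expected curvature-induced streamline
  attrition discussed above.
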