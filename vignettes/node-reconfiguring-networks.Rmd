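---
title: "Node-reconfiguring multilayer networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Node-reconfiguring multilayer networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlbrainnet)
```

## The problem

Functional brain networks use Regions of Interest (ROIs) — sets of fMRI
voxels — as nodes, and the ROI time series is the average of its voxel
series. Averaging is only faithful when the voxels inside an ROI are
functionally homogeneous, i.e. strongly correlated. Static atlases violate
this assumption because the boundaries of correlated voxel groups move on
time scales of seconds. `mlbrainnet` implements a model in which ROI
boundaries are re-optimized inside every time window, and the windows
become the layers of a multilayer network: intralayer edges carry
functional connectivity, interlayer edges carry the spatial overlap of
ROIs in consecutive windows, so the reorganization of the parcellation is
itself part of the network.

## Homogeneity measures

**Spatial consistency** of an ROI $I$ is the mean Pearson correlation over
all distinct voxel pairs,

$$\phi(I) = \frac{1}{|I|(|I|-1)} \sum_{u \ne v \in I} C(u, v),$$

implemented in `spatialConsistency()`. It is undefined for $|I| < 2$;
single-voxel ROIs are treated as artifacts and removed by
`excludeSingleVoxelRois()` before any analysis. A zero-variance voxel
series has no defined correlation; the package assigns such pairs
correlation 0 and warns, which avoids NaN propagation without biasing
non-degenerate data.

**Regional homogeneity (ReHo)**, `regionalHomogeneity()`, is Kendall's
coefficient of concordance

$$W = \frac{12 \sum_i (R_i - \bar R)^2}{K^2 (n^3 - n)}$$

over the $K$ series formed by a voxel and its face-sharing masked
neighbors ($K = 7$ in the interior; at mask boundaries $K$ shrinks to the
available neighbors plus the center). Ranks are midranks and no
tie-correction term is applied, matching the plain form of the statistic.
$R_i$ is the rank sum at time point $i$ over the $K$ series.

## ROI definition

Five node-definition routes share the `Parcellation` container:

1. **Greedy, weighted mean consistency** — region growing from seeds with
   the priority
   $$PV(I, i) = \frac{\sum_{I'} |I'| \phi(I')}{\sum_{I'} |I'|}
   - \lambda \frac{\sum_{I'} |I'|^2}{(\sum_{I'} |I'|)^2},$$
   evaluated as if candidate voxel $i$ were already in ROI $I$. The first
   term drives homogeneity, the second keeps the ROI size distribution
   narrow. Summands $|I'|\phi(I')$ for single-voxel ROIs are taken as 0
   ($\phi$ is 0/0 there); this gives fresh seeds a growth advantage, which
   suits the goal of avoiding single-voxel remnants.
2. **Greedy, minimum correlation** — the priority is the lowest
   correlation between the candidate and any current ROI member. It needs
   no size regularization.
3. **NCUT spectral clustering** (`craddockCluster()`) — the 6-neighbor
   voxel graph with correlation weights is thresholded (default 0.2,
   which also removes all negative weights) and repeatedly bisected by
   normalized cut; the largest current cluster is split next, so pieces
   are cut off the dominant component, and the requested cluster count is
   an upper bound for the splitting loop.
4. **Random region-grown parcels** (`generateRandomParcellation()`) — the
   data-blind reference.
5. **Static label volumes** (`readParcellation()`) — any integer NIfTI
   atlas; replicated over layers it yields a multiplex network. The
   filtered-multiplex baseline (`filterStaticParcellation()`) keeps the
   most consistent atlas ROIs within a voxel budget, adding in consistency
   rank order until the next ROI would overflow the budget.

Greedy growth details that the formulas leave open are resolved as
follows, all covered by tests: candidates are (ROI, voxel) pairs over
face-adjacent unassigned voxels; the pair with the highest priority is
popped; ties break by ascending ROI label, then voxel linear index, so
results are fully deterministic; queue entries of an assigned voxel are
discarded; the thresholding step accepts a popped candidate only when its
average correlation to the target ROI is among the N% highest of the
average-correlation values of all currently queued pairs (N = 30 in the
reference configuration; thresholding is off by default in the API). The
reference set for "among the N% highest" is genuinely ambiguous in the
region-growing literature; taking the current queue, recomputed at each
pop, keeps the criterion adaptive to the growth stage and is isolated in
`thresholdAccept()`. "Among the N% highest" is read by enumeration — at
least the $\lfloor N/100 \cdot n\rfloor$-th largest reference value — and
a rejected pair does not re-enter the queue.

Seeds come from `selectRehoSeeds()`: the voxel with maximal ReHo inside
each ROI of a template parcellation, which spreads seeds across the mask
and fixes the ROI count.

### A note on $\lambda$ at small problem sizes

The regularization term is scaled by the squared total voxel count, so the
pressure it exerts depends on the absolute problem size: $\lambda = 100$
balances the two terms at whole-brain voxel counts (tens of thousands of
voxels, ~250 ROIs) and is the package default. On the few-hundred-voxel
grids used for validation, the same $\lambda$ dominates the homogeneity
term and forcibly equalizes ROI sizes. The planted-partition recovery
tests therefore run the weighted-mean-consistency priority with
$\lambda = 0$: they assess whether the homogeneity term alone recovers the
planted voxel groups, whose sizes are deliberately not equal. This is a
property of the term's scaling, not a tuning choice; users working on
small grids should scale $\lambda$ down accordingly.

## The multilayer network

`splitWindows()` cuts the recording into non-overlapping windows (default
80 samples = 8 s at the 100 ms default sampling interval; trailing samples
are discarded). Per layer, `buildNetwork()` computes ROI mean series and
the complete intralayer correlation graph; between consecutive layers the
interlayer edge weight is the Jaccard index
$|I_t \cap I'_{t+1}| / |I_t \cup I'_{t+1}|$, with no edge when the voxel
sets are disjoint. Node identity is (layer, label): labels are not
comparable across layers for reconfiguring methods. Interlayer edges exist
only between consecutive layers; overlaps across longer lags belong to the
trajectory analysis. With a static parcellation the construction
degenerates to a multiplex network — one unit-weight interlayer edge per
node — which the tests assert exactly.

## Analytics

* `stabilityScore()` — the heaviest interlayer edge from a node to the
  next layer; 0 when the ROI disperses, 1 when it persists unchanged.
  Worked boundary cases: keeping 70% of the voxels with nothing added
  scores 0.7; keeping all voxels while 30% newcomers merge in scores
  $1/1.3 \approx 0.77$; losing 30% while gaining 70% scores
  $0.7/1.7 \approx 0.41$. Nodes on the last layer have no score and are
  excluded from pooled summaries.
* `trajectory()` — best Jaccard overlap of a reference ROI against every
  later layer, computed from voxel sets directly; it can reveal ROIs that
  shatter and later return to their original configuration. The default
  minimum reference size is 5 voxels.
* `pairwiseStability()`, `meanIntralayerCorrelation()` and
  `binnedCurve()` relate interlayer stability to intralayer coupling.
  Binning uses a closed first bin $[0, 0.1]$ and half-open successors
  $(0.1, 0.2]$, …; x = 0.1 belongs to the first bin, x = 0.1001 to the
  second. Values are pooled over layers and runs before binning, not
  averaged per layer first.
* `interlayerWeightCdf()` — pooled empirical CDFs of interlayer weights
  or stability scores.
* `correlationDistributions()` / `excessArea()` — within- versus
  between-ROI correlation samples and the integrated positive difference
  of their densities (histograms over $[-1, 1]$, default bin width 0.01;
  between-ROI pairs are uniformly subsampled with an explicit seed once
  their number exceeds `maxPairs`).
* `consistencyCarryover()` — applies window-t boundaries to windows t and
  t+1 and compares per-ROI consistency. For data-driven parcellations the
  mean change is negative (boundaries fit the window they were optimized
  in); for random or static parcels it is zero in expectation, which the
  acceptance tests verify over 60 generator seeds.

## The synthetic generator

`generateReconfiguringDataset()` emulates the planted-structure simulation
the clustering methods assume: region-grown random parcels; an independent
standard white-noise series $x(t)$ at each ROI seed; every other voxel at
Euclidean distance $d$ from its seed carries
$y(t) = \tfrac{G(d)}{G(0)} x(t) + \bigl(1 - \tfrac{G(d)}{G(0)}\bigr) n(t)$
with $G$ the zero-mean Gaussian density of variance 5 (voxel units
squared) and $n(t)$ voxel-specific white noise. The simulation recipe
fixes neither the series length nor the noise amplitude, so both are
config parameters (`nTimepoints`, `noiseAmplitude`, default sd 1);
`noiseAmplitude` well below 1 defines the low-noise regime used in the
recovery tests (0.05 there). Multi-window data are generated window by
window and concatenated — there is no temporal autocorrelation across
window boundaries — and between windows a configurable fraction of seeds
relocates to random masked voxels before the parcels are regrown.

What the generator does *not* emulate: hemodynamic responses, scanner
noise spectra, physiological confounds, spatial autocorrelation beyond the
planted kernel, or overlapping/graded functional sources. Passing the
planted-recovery and carryover tests therefore shows the algorithms are
correct on data satisfying their own assumptions; it does not certify
performance on real fMRI.

## Problem sizes and numerical choices

Validation runs use grids up to $10^3$ voxels, 2–10 planted ROIs and
160–240 time points, where every algorithm completes in seconds and the
whole suite in well under a minute; these sizes give the statistical
checks (null expectation of ReHo, carryover symmetry over 60 seeds)
comfortable resolution. Consistency carryover checks use 20-sample
windows: shorter windows make consistency estimates noisier and hence
the window-specific optimization effect more visible at small grids.

Other numerical policies: voxel coordinates are 1-based (i, j, k) with R
column-major linear indices throughout, recorded in the pipeline
manifest; correlations are computed via unit-norm centered series so the
greedy updates are exact dot products; NCUT bisection solves the
normalized Laplacian eigenproblem densely (`eigen`) and sweeps the
second eigenvector for the best split, which is exact on the component
sizes used here; simultaneous claims in round-based random growth go to
the lowest ROI label; all RNG flows from explicit seeds and fixed seeds
reproduce volumes bit-identically.

## Limitations

* The greedy queue is re-scored in full at each pop; this is exact and
  fast at validation scale but would need an incremental heap plus
  compiled code for whole-brain voxel counts.
* Dense eigendecomposition limits NCUT components to a few thousand
  voxels per split.
* Windows are non-overlapping with a fixed length; no sliding windows,
  and no interlayer coupling parameter as used in multislice modularity
  methods.
* No group-level statistics across subjects; the pipeline processes one
  volume per run, and batching is a loop in the CLI script
  (`inst/scripts/mlbrainnet.R`).
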