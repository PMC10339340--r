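---
title: "Counting membrane-protein subunits by dual-color colocalization SMLM"
author: "dcColoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting membrane-protein subunits by dual-color colocalization SMLM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcColoc)
```

## The counting problem

Single-molecule localization microscopy (PALM) resolves individual
fluorescent-protein emissions, but counting subunits from the number of
blinking events is notoriously fragile: recall rates below one, blinking
that spreads one molecule over many frames, and background events all
corrupt the count. The dual-color colocalization (DCC) strategy sidesteps
event counting entirely. Every subunit of the protein of interest carries
two fused fluorescent proteins: a bright **marker** (M, e.g. mVenus) whose
clusters define which complexes are observed, and a photoactivatable
**indicator** (F, e.g. PAmCherry) whose *per-complex* detection
probability carries the stoichiometric information.

If the indicator on one subunit is detected with recall rate $p$, a
complex of $n$ independent subunits shows at least one indicator signal
with probability

$$R \;=\; \frac{N_{MF}}{N_M} \;=\; 1 - (1-p)^n ,$$

where $N_M$ is the number of marker clusters and $N_{MF}$ the number of
marker clusters with an indicator cluster within a distance cutoff. The
measured quantity is a *cumulative* probability, so recall rates well
below 0.5 remain usable, and temporal assignment of blinking events to
molecules is never needed. Equivalently, $\ln(1-R)$ is linear in $n$ with
slope $\ln(1-p)$.

Because two fused fluorophores can interfere with each other or be
truncated together, the model is extended with a **coefficient of
modification** $m$: each subunit's fluorophore pair is intact with
probability $1-m$, and a modified subunit contributes neither marker nor
indicator. Conditioning on marker visibility (at least one intact
subunit):

$$R \;=\; \sum_{k=1}^{n} \frac{\binom{n}{k}(1-m)^k m^{\,n-k}}{1-m^n}
  \left(1-(1-p)^k\right).$$

`expectedRatio(n, p, m)` implements this; the $k$-weights sum to one, the
expression reduces exactly to the first equation at $m = 0$, and $R$ is
strictly increasing in $n$ and $p$ and decreasing in $m$ (all verified in
the test suite).

## From localizations to ratios

The pipeline consumes per-channel localization tables (frame, x, y,
intensity; internally always nanometres, frames 0-based) in three
dialects (CSV, an HDF5 layout storing pixel coordinates, and a MATLAB v5
container), and proceeds per recording:

1. **Chromatic-aberration correction** (`readLocalizations(...,
   caModel=)`, `applyChromaticAberration`). Lateral chromatic aberration
   displaces the red channel relative to the green by an amount that is
   linear in position. The model is separable (dx depends on x only, dy
   on y only) and is fitted by ordinary least squares to deviations of
   mutually-nearest bead pairs (`pairBeads`,
   `fitChromaticAberration`) pooled over bead-only recordings
   (`runCAFit`), ideally 500+ positions across the field. The deviation
   is regressed on the *corrected channel's observed* coordinate, which
   makes subtract-at-observed-coordinate correction an exact inverse of a
   linear field rather than leaving an $O(\mathrm{slope}^2)$ residual; the
   price is a reparametrization (a field of slope $s$ applied at true
   coordinates is estimated as $s/(1+s) \approx s$ for $|s| \ll 1$),
   which is irrelevant for correction quality.
2. **Clustering** (`findClusters`). Localizations below an intensity
   threshold are discarded; the rest are clustered purely spatially by
   DBSCAN on (x, y). The implementation is deterministic: points are
   visited in ascending row order and a border point reachable from two
   clusters joins the one discovered first. Beads are found with a high
   intensity threshold and `min_samples` of roughly a quarter of the
   frame count (beads emit in every frame); protein signals with low
   thresholds. `splitBeadsAndSignals` separates the two by mean intensity
   and frame persistence.
3. **Drift correction** (`extractDrift`, `applyDrift`). Each bead's
   per-frame position is interpolated linearly over missing frames
   (constant at the ends), frame-to-frame displacements are averaged
   across beads and cumulated, anchored at (0,0) in frame 0. Each bead's
   cumulated displacement telescopes to position minus initial position,
   so localization noise does not accumulate with frame number. Drift is
   computed per channel — the two channels are recorded sequentially and
   see different drift.
4. **Colocalization** (`getColocalizationRatio`). Marker clusters are
   restricted to rectangular ROIs around the cell (half-open
   containment, evaluated on marker centroids only so that indicator
   partners just outside an ROI edge still count). A marker is
   colocalized if an indicator centroid lies within the cutoff
   (default 100 nm); matching is one-to-one and greedy by ascending
   distance — the conservative choice when counting complexes, since one
   indicator cluster cannot certify two complexes.

A recording whose axial refocus check reports an offset above 100 nm is
discarded as invalid (`qcFilterRecordings`, or the `zOffset` argument of
`analyzeRecording`); exclusions are logged.

## Calibration and inference

Reference proteins of known state (e.g. monomer–tetramer standards)
provide per-recording ratios from which `fitPM` estimates $(p, m)$ by
least squares under box constraints, started from a small grid to guard
against the shallow $p$/$m$ trade-off valley; at least two distinct
states are required (a single state cannot identify two parameters).
`referenceBootstrap` resamples recordings with replacement *within each
state group* and refits, giving percentile (2.5/97.5%) confidence
intervals; least squares rather than a likelihood is used because each
ratio is an aggregate over hundreds of clusters and approximately
Gaussian.

For a protein of unknown state, the **coefficient of mismatch** for each
candidate $n$ is the squared relative deviation of the mean observed
ratio from the model expectation,

$$\mathrm{COM}(n) = \left(\frac{\bar R - E_n(\hat p, \hat m)}
  {E_n(\hat p, \hat m)}\right)^2 ,$$

zero at a perfect fit and scale-free; the minimizing $n$ is the call,
with ties broken toward the smaller state. The mean $\bar R$ weights
recordings (cells) equally, matching the per-recording bootstrap.
`comBootstrap` resamples the protein-of-interest ratios (and optionally
the calibration set, propagating its error) and reports the fraction of
replicates electing each state. `ksCompare` offers the distributional
alternative: a two-sample Kolmogorov–Smirnov comparison of the
protein-of-interest ratios against each reference protein's ratios, the
most compatible state having the smallest $D$ (largest p-value). The
exact functional form of the mismatch and the interpolation of missing
bead frames are this package's documented choices; both sit behind small
interfaces and can be swapped.

Candidate states default to $1..6$, covering the usual monomer–tetramer
standards with margin. Bootstrap counts default to 1,000.

## The simulator

`simulateRecording` generates a dual-color recording with complete ground
truth under typical acquisition conditions for this kind of
experiment: a
41 × 41 µm field (512 × 512 pixels at 80 nm), 4,000 marker and 9,000
indicator frames by default, 3–6 always-on fiducial beads placed outside
the cell region, per-channel drift (none/linear/random-walk), a linear
chromatic-aberration field applied to the indicator channel at the
emitter's physical position, and sparse Poisson background impurities
kept outside a clean margin around the cell (sample preparation and
prebleaching keep impurities rare; a stress mode scatters them
everywhere). Detection follows
the DCC model exactly: subunits are intact with probability $1-m$,
marker visibility requires one intact subunit (marker recall defaults to
1, reflecting the bright marker channel), and each intact subunit fires
its indicator with probability $p$. Every detected fluorophore emits one
burst of geometrically distributed length (mean 3 frames, matching the
~86 ms frame period and multi-frame blinking) with isotropic Gaussian
localization noise (default σ = 15 nm; beads
σ/√(intensity factor), the photon-statistics scaling).

Complexes are placed by a jittered-grid (blue-noise) sampler enforcing a
minimum separation of four times the colocalization cutoff, so that
validation runs are free of ambiguous matches; a crowding stress mode
disables this. What the simulator does *not* emulate: dark-state blinking
kinetics and photon-budget camera noise (one burst per detected
fluorophore abstracts the photophysics — the DCC method is deliberately
burst-count-agnostic), axial (z) structure, nonlinear chromatic
aberration, and spatially structured background. Passing tests therefore
demonstrate correctness of the analysis chain under the model's own
assumptions, not robustness to every instrument artifact.

`simulateRatioTable` draws recording-level counts directly from the
detection law (exact and fast, for calibration studies);
`simulateBeadField` generates the stacked two-color bead recordings used
for chromatic-aberration determination, with a per-position pairing
noise modelling stage jitter between stacked recordings.

## Study configurations and numerical choices

`studyConfig()` is the analysis configuration used by the package's own
validation studies: signal clustering with `eps` of four times the
localization σ (60 nm; a burst's localizations then fragment with
probability below 2%) and `min_samples = 1` — with a prebleached, ROI-
excluded background every indicator localization is signal, and
`min_samples = 1` keeps per-fluorophore detectability independent of
oligomer size, which the DCC model assumes. For real data with residual
background the package defaults (`eps` 30 nm, `min_samples` 2) are the
safer starting point; both are plain config values. The colocalization
cutoff of 100 nm is ~5× the residual registration error of the simulated
studies and well below the 400 nm complex separation.

`simulateInferenceStudy` runs the whole chain — bead-field CA fit,
reference and protein-of-interest recordings through CA/drift/cluster/
ratio, calibration, COM election — at a scaled-down acquisition size
chosen for routine verification: 150 marker / 250 indicator frames,
3 beads, 300 complexes and 12 recordings per protein, 4 reference states.
The package's validation studies use 100 calibration repeats (bootstrap
depth 400) and 50 inference runs per true state; Monte-Carlo model
checks use $10^5$ complexes per parameter cell.

Other numerical choices: optimizer L-BFGS-B with objective tolerance
near machine precision and a 3 × 2 multistart grid; bootstrap refits
start from the full-data estimate; cluster centroids are unweighted
means (the simplest defensible estimator); DBSCAN neighbourhoods are
inclusive (a point is its own neighbour) and ties everywhere break
toward the smaller index, making every stage reproducible bit-for-bit
from seeds.

## Limitations

* $m$ is modelled per subunit (a modified subunit loses both
  fluorophores), consistent with the conditioning on intact subunits; if
  interference silenced only one fluorophore of a pair the calibration
  would absorb part of the effect into $\hat p$.
* The COM compares only the mean ratio; distributional information is
  delegated to the KS comparison.
* Percentile bootstrap intervals can slightly undercover for $m$ near
  its boundary at small recording counts.
* The chromatic-aberration model is linear and separable; field
  curvature would need a richer model than this package provides.
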