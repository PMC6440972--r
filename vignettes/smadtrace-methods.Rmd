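---
title: "Models and methods behind smadtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smadtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smadtrace)
```

## The biological system and the measurement

TGF-beta binding to its receptors triggers phosphorylation of SMAD2, which
complexes with SMAD4 and translocates to the nucleus, where it activates
direct target genes such as *ctgf* (connective tissue growth factor). In
dual-reporter single-cell assays this is read out with two luciferases
imaged on alternating exposures within a 5-minute cycle: a
Nanoluciferase-SMAD fusion (dox-inducible) whose nuclear-to-cytoplasmic
(N/C) intensity ratio reports translocation, and a short-lived firefly
luciferase knocked into the *ctgf* locus reporting transcription. The N/C
ratio is the central observable because any factor common to both
compartments — substrate decay, expression level, illumination drift —
cancels in the quotient.

smadtrace provides (i) a phenomenological generator of such recordings
with known per-cell ground truth, (ii) a movie-analysis pipeline
(segmentation, tracking, trace extraction, cross-talk correction),
(iii) per-cell response features, (iv) transient-versus-sustained
classification by correlation-distance k-means with silhouette
validation, and (v) dose-response and class-fraction statistics. Because
no public dataset exists for this assay, every stage is validated by
parameter recovery against the generator's truth.

## The trace generator

The generator is deliberately phenomenological: it reproduces the
statistical structure of the observables, not receptor/SMAD biochemistry
(no ODE model, no enzyme kinetics beyond one exponential).

**SMAD translocation.** Each cell's N/C ratio sits at baseline 1.0 (the
fusion is distributed across both compartments before stimulation; the
baseline is not reported numerically anywhere we know of, so 1.0 is a
neutral default) and rises after stimulation by a pulse

\[ r(t) = 1 + A\,\frac{g\big(u(t)\big)}{g(u^*)},\qquad
   g(u) = e^{-u/\rho} - e^{-u}, \]

a difference of exponentials (fast rise, slow decay; shape ratio
\(\rho = 6\)) time-rescaled per cell so that the drawn peak time \(T\) and
peak height \(A\) are exact. The pulse starts `smad_onset_delay` (10 min)
after ligand addition — receptor binding and phosphorylation are not
instantaneous, and the basal window defined below presupposes a
response-free first cycle. \(T\) is gamma distributed (SMAD4: mean 55 min,
CV 0.33; SMAD2: mean 66 min, CV 0.35) and \(A\) lognormal (mean 1.0,
CV 0.73) scaled by a Hill function of the TGF-beta dose
(\(K = 50\) pM, coefficient 1, so 5 pM is near floor and 500 pM near
saturation). Gamma and lognormal are the standard minimal choices for
positive times and amplitudes specified only by mean and CV. Compartment
intensities conserve total fusion protein
(\(\mathrm{nuc} + \mathrm{cyt} = 2L\), with \(L\) the per-cell level,
lognormal CV 0.3, linear in dox dose relative to 2 ng/ml), are multiplied
by a common substrate-decay exponential (half-life 600 min) and by
independent per-timepoint lognormal noise.

**Noise.** Multiplicative lognormal noise with CV 0.02 per compartment
per timepoint. Compartment traces are means over hundreds of pixels, so
even substantial per-pixel shot noise averages to a small relative error
on the mean; 2% leaves room for biological and focus fluctuations on top.
Pixel-level Poisson noise appears only in rendered movies.

**ctgf response.** Transcription initiates a gamma lag (mean 7 min,
CV 0.5) after the cell's SMAD peak. Transient cells (87%) mount a single
pulse — sine rise from initiation to a peak 210 min post-stimulus (middle
of the reported 3-4 h), cosine decay touching basal exactly at 480 min
(8 h). The sine rise has nonzero slope at onset, so the initiation time
is sharp; the cosine lands on basal with nonzero slope, so the return
time is sharp. Sustained cells (13%) mount a weaker first pulse (x0.8),
decay only to a plateau (0.3 of their first peak), and launch a second
wave of equal height with onset jittered uniformly over
[480, 720] min post-stimulus ("less synchronous"); whether the second
wave's amplitude relates to the first is not reported, so equality before
jitter is the neutral choice. Amplitudes are lognormal (mean 1000 a.u.,
CV 0.6) with the same Hill dose scaling; basal is lognormal
(mean 100 a.u., CV 0.2).

**Cross-talk.** The raw Fluc channel receives 1.5% of the total Nluc
signal (`apply_crosstalk()`); `crosstalk_correct()` is its exact
algebraic inverse.

**Determinism.** Every cell draws from its own substream derived from the
cohort seed, so cohorts are bit-identical under a fixed config + seed and
single cells can be regenerated without shifting their neighbours.

**What the generator does not emulate.** Cell division, death, migration
out of frame, focus drift, day effects, the interleaved 3-min/2-min
exposure grids (a single shared 5-min grid is used, since analysis is
per-cycle), or any mechanistic coupling between SMAD dynamics and ctgf
amplitude (they are drawn independently — deliberately, since the paper
reports them uncorrelated). Passing recovery tests therefore shows the
pipeline is correct and well calibrated on data with this statistical
structure; it cannot show robustness to artefacts the generator omits.

## Movie analysis

Rendered movies draw each cell as a nuclear disc (radius 6 px) at the
nuclear Nluc value inside a cytoplasmic surround (radius 14 px) at the
cytoplasmic value, with Fluc uniform over the cell, constant background,
optional Poisson shot noise, and small reflected random walks.

Segmentation convolves each frame with a bank of center-surround
disc-matched filters (radii 6/10/14 px, max-pooled) — a concrete reading
of "a family of cell-like filters" — and binarizes by a local-mean
adaptive threshold whose offset scales with the maximum response, making
masks invariant to global intensity scaling. Components under 30 px² are
dropped. Because a resting cell has equal nuclear and cytoplasmic
concentrations, the nucleus is not separable from the cytoplasm by
intensity at baseline; quantification therefore uses a nuclear disc of
known radius (`nucleus_radius`, an acquisition parameter) centered on the
detection centroid, with the cytoplasmic annulus (gap 2 px, width 5 px)
outside it. Pixels contested between neighbouring annuli go to the
nearest centroid; pixels inside any nucleus are never cytoplasm.
Background is the per-frame median of off-cell pixels.

Tracking links detections frame-to-frame by an exact minimum-cost
assignment (shortest augmenting path) capped at `max_link_dist`; tracks
shorter than `min_track_len` are discarded *before* gap closing so
spurious detections cannot bridge real tracks; gaps up to `max_gap`
frames are closed greedily with linear interpolation and flagged. Because
assignment is one-to-one, merges cannot occur and splits simply spawn new
track ids — simpler than a full merge/split resolver, and sufficient for
non-dividing, slowly moving cells.

## Response features

All features automate annotations that were done manually in the
original analyses; the automation rules are the package's central
interpretive decisions and all their parameters are exposed:

- *Basal level*: mean of the three timepoints centered on stimulation.
- *Peak*: argmax of the 3-point moving-average-smoothed trace within a
  search window (SMAD 0-4 h, ctgf 0-12 h post-stimulus; windows read off
  the reported response ranges), earliest index on ties; peak level is
  the mean of the three raw points around it; boundary peaks are flagged
  censored and the cell excluded (reported, never silently dropped).
- *Response and fold change*: peak minus basal; peak over basal.
- *Initiation / return*: first run of m = 3 consecutive points above
  (below) basal + 2 SD of the pre-stimulation points, after stimulation
  (after the peak). With noise-free traces the SD is zero and a tiny
  relative floor (1e-8) keeps the rules defined. A trace that never
  exceeds threshold has neither initiation nor return; an undefined
  return within the recording is the signature of a sustained cell.
- *Mean SMAD level*: mean total Nluc over the 12 h post-stimulation.
- CVs use the sample SD (n-1).

Two intrinsic limitations of these estimators are worth knowing. First,
the 3-point peak average underestimates pulses whose rise is narrower
than the averaging window, i.e. cells peaking within ~4 cycles of
stimulation; recovery tests bound those cells separately. Second, under
measurement noise the smoothed argmax jitters asymmetrically toward the
pulse's flat decay side, giving peak-time cohort means a small late bias
(about +1 to +2.5 min at the default noise) and slightly inflated CVs
relative to truth — the price of automating an annotation the original
analysis did by hand.

## Classification

Traces are cropped to the post-stimulation window, max-normalized (so
dynamics rather than amplitude drive the classes; absolute mode is
available), and clustered by k-means under correlation distance
\(d = 1 - r_{\mathrm{Pearson}}\), k = 2. Seeding is the k-means++ scheme
transplanted to correlation distance (next seed drawn with probability
proportional to squared distance to the nearest seed); the centroid is
the arithmetic mean trace (a Fréchet mean under correlation distance is
ill-defined); iteration runs to an assignment fixpoint; the best of 50
restarts by total within-cluster distance wins; everything is
deterministic under the seed. Each cell gets a silhouette value
\(S_i = (b_i - a_i)/\max(a_i, b_i) \in [-1, 1]\), tested against an
O(n²) brute-force oracle, and the whole clustering is tested against the
exhaustive best 2-partition for small n. Cluster names are content-based:
the cluster whose mean normalized trace is higher late (8-12 h
post-stimulus) is "sustained", so labels cannot depend on cluster-id
permutations. Class fractions across conditions are compared by Pearson
chi-squared without continuity correction; class-level feature
comparisons use Welch's t-test (the unequal-variance form, since class
sizes and variances differ ~7-fold).

## Dose-response

Per-dose summaries report the responder fraction (cells with a defined
ctgf initiation — a concrete stand-in for "active single cells", which is
otherwise unspecified) and medians/IQRs of the SMAD and ctgf response
amplitudes among responders: graded medians at near-constant responder
fractions indicate analog rather than digital dose encoding. Amplitude
and timing couplings are Pearson correlations (linear fits are what the
original figures show) with Spearman alongside for robustness.

## Numerical choices and problem sizes

Validation cohorts use 500 cells for timing/amplitude recovery (the SE
of a mean at SD ~18 min is then under 1 min), 301 cells for mixture
recovery, 300 noise-free cells for exactness checks, and a 20-cell,
61-frame rendered movie for segmentation/tracking identity recovery —
sizes at which every recovered quantity's sampling error is comfortably
inside its target band while the whole suite stays quick to run.
Chi-squared null calibration uses 1000 replicate 2x2 tables at n = 1000
per condition, large enough that the discreteness of the p-value
distribution is below the Kolmogorov-Smirnov resolution at alpha = 0.01.

## Reproducing the headline numbers

`scripts/acceptance.R` re-simulates the default cohorts at a
caller-supplied seed, runs the full pipeline, and writes the recovered
quantities (timing means/CVs for both isoforms, the SMAD-peak-to-ctgf
lag, the response-amplitude CV, the regressed cross-talk percentage, and
the mean transient return time) as JSON. The README shows a worked
example with the numbers it prints.
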