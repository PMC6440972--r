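# smadtrace

Single-cell analysis of SMAD4/2 nuclear translocation and *ctgf*
transcriptional dynamics from dual-reporter bioluminescence time-lapse
recordings — with a ground-truth synthetic-data generator, so every stage
of the pipeline is verifiable by parameter recovery.

## The problem

TGF-beta signaling drives SMAD2/SMAD4 complexes into the nucleus, where
they activate direct target genes such as *ctgf*. Dual-luciferase imaging
reads both layers in the same cell on a 5-minute cycle: a
Nanoluciferase-SMAD fusion whose **nuclear-to-cytoplasmic (N/C) ratio**
reports translocation, and a short-lived firefly luciferase in the *ctgf*
locus reporting transcription. Questions this package quantifies, cell by
cell:

- how variable are translocation timing and amplitude (gamma-distributed
  peak times, lognormal amplitudes; timing tightly controlled, amplitude
  broad, CV ~0.7);
- how quickly transcription follows the SMAD nuclear peak (a lag of a few
  minutes);
- whether single-cell *ctgf* responses are **transient** (one pulse,
  back to basal by ~8 h) or **sustained** (weaker first pulse plus a
  delayed second wave), classified by k-means with correlation distance
  `d = 1 - Pearson r` at k = 2, validated per cell with the silhouette
  `S_i = (b_i - a_i) / max(a_i, b_i)`;
- how TGF-beta dose (5 pM-5 nM) is encoded: graded per-cell amplitudes at
  a near-constant responder fraction (analog, not digital);
- whether class fractions shift with SMAD expression level (chi-squared
  on condition-by-class tables; Welch t-test on levels between classes).

Because raw recordings of this kind are not publicly deposited, the
package ships a calibrated generator (`simulate_cohort()`, optionally
rendered to two-channel TIFF movies by `render_movie()`) carrying per-cell
ground truth, plus the full measurement pipeline: nuclear segmentation
with a matched-filter bank, exact-assignment tracking with gap closing,
compartment trace extraction, 1.5% Nluc-to-Fluc cross-talk correction,
response features, classification, and dose-response statistics.

## Worked example

```r
library(smadtrace)

cfg   <- sim_config(n_cells = 301, seed = 7)   # 24 h at 5 min, 5 nM TGF-beta
ts    <- simulate_cohort(cfg)                  # long tibble + ground truth
feats <- quantify_cohort(ts)                   # per-cell response features

cohort_stats(feats[!feats$excluded, ],
             c("smad_peak_time", "nc_response", "ctgf_init_time", "return_time"))
#>   feature            n   mean      sd    cv
#> 1 smad_peak_time   301  59.8   24.6   0.412
#> 2 nc_response      301   1.08   0.849 0.788
#> 3 ctgf_init_time   301  66.2   20.9   0.316
#> 4 return_time      301 540.   167.    0.310

cls <- classify_traces(ts, k = 2, seed = 7, features = feats)
glance(cls)
#>       k     n  seed restarts inertia mean_silhouette n_transient n_sustained
#> 1     2   301     7       50    4.41           0.932         268          33
```

Read: SMAD4 translocation peaks just under an hour post-stimulus with
tight timing but broad amplitude (CV ~0.8 here, including measurement
noise); *ctgf* initiates ~6 min after the SMAD peak on average; k-means
at k = 2 splits 268 transient / 33 sustained (89%/11% against a
generative 87%/13%) with a mean silhouette of 0.93, i.e. a clean
two-class structure. `tidy(cls)` gives per-cell labels and silhouettes;
`autoplot(cls)` and `autoplot(ts)` draw the class means and traces.

A JSON-configured end-to-end run (simulate → quantify → classify →
dose-response → report, or segment rendered TIFFs instead) is
`run_pipeline("config.json", out_dir = "out")`; a thin CLI wrapper lives
at `inst/scripts/smadtrace`.

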