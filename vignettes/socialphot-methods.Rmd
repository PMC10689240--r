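---
title: "Methods: signal model, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal model, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialphot)
```

This vignette documents the models behind `socialphot`, the parameters that
matter, the numerical choices made where several were defensible, and what
the synthetic-data generator does and does not emulate.

## Signal model

Bulk fluorescence from a population of GCaMP-expressing neurons is modeled
as a slow multiplicative drift (photobleaching) carrying fractional calcium
transients plus acquisition noise:

$$F_\mathrm{raw}(t) = D(t)\,\bigl(1 + T(t)\bigr) + \varepsilon(t),
\qquad D(t) = F_0\left[(1-A) + A\,e^{-t/\tau_\mathrm{bleach}}\right],$$

with $T(t)$ the summed transient contribution of behavior bouts and
$\varepsilon \sim \mathcal N(0, \sigma^2)$ i.i.d. Bleaching is multiplicative
because it scales the fluorophore pool, not an additive offset. Under this
model the exact fractional change is
$\Delta F/F = (F_\mathrm{raw} - D)/D = T + \varepsilon/D$, which is what the
preprocessing chain estimates.

### Baseline estimation

`estimate_baseline()` slides a window of `window_fraction` (default 0.25) of
the total recording across the trace; within each window the configured
quantile of the raw signal becomes a baseline anchor placed at the center of
the (edge-truncated) window, and anchors on a stride grid
(`stride_fraction`, default 0.2 of the window) are interpolated by a natural
cubic spline. Two regimes matter:

- **Transient-bearing traces** (the normal case): transients are
  positive-going, so a *low* quantile (default 0.10) tracks the lower
  envelope — the drift — while ignoring bouts of elevated signal.
- **Transient-free traces**: the low quantile is, by construction, biased
  below the drift, and because the drift's slope changes over the session
  the bias is time-varying; the *median* (`quantile = 0.5`) is the unbiased
  setting there, since the median of a monotone signal inside a window
  equals its value at the window center. Validation against the generator's
  known drift, and the null-calibration study below, therefore run at
  `quantile = 0.5`; this is a property of envelope estimators, not a free
  parameter tuned per dataset.

Edges use truncated windows rather than padding (no fabricated data), and
anchors sit at the truncated window's true center, which keeps the estimate
unbiased to within spline-extrapolation error over the outermost quarter
window (measured below 0.4% of the drift amplitude on drift-only traces).
Traces with missing samples are rejected rather than imputed.

### z-scoring

`zscore_trace()` standardizes ΔF/F over the whole recording with the
sample-SD (n − 1) convention, producing Fz with mean 0 and SD 1 to within
1e-9. Z-scoring is per recording file; concatenating recordings before
standardization would mix noise regimes across files. Note one consequence
used repeatedly below: because the *whole trace* has mean zero, the quiet
baseline between responses sits slightly **below** zero whenever the session
contains positive transients.

## Event-aligned metrics

PETHs resample Fz around each bout (linear interpolation onto a bin grid;
defaults: 10 s pre, 20 s post, 0.2-s bins — the window and bin are
configurable because no single choice suits both second-scale investigation
bouts and 10-s presentations). Averaging is hierarchical — trials → animal
mean → grand mean ± s.e.m. across animals — so animals, not trials, are the
unit of replication. Trials keep raw Fz; nothing is renormalized per trial.

The pointwise test is a two-sided one-sample t-test of the per-animal means
against Fz = 0 in each bin, corrected across bins with the
Benjamini–Hochberg step-up rule at q = 0.05; the displayed mask additionally
requires a positive grand mean, flagging only significantly *increased*
responses. BH is implemented directly (sorted p-values, reject the largest
$k$ with $p_{(k)} \le kq/m$; ties share fate) and is cross-checked in the
tests against brute-force enumeration and `stats::p.adjust`. Bins with zero
variance get p = 1 when the mean is 0 (and p = 0 otherwise) rather than NaN.

Trial responses normalize each bout by the "signal at time 0", taken as the
mean of the two samples straddling the onset — a single sample would make
the normalization hostage to one noise draw. A trial responds when the
normalized trace reaches Z ≥ 1 (inclusive) before the bout ends; "% of
trials respond" pools bouts (per-animal averaging can be layered on top by
the caller — pooling is the default because sessions contribute unequal
trial counts either way). Bouts shorter than one sample period are skipped
with a warning count.

The preference index divides the contrast of the target stimulus against
the mean of the other two by the sum of their magnitudes, so it is bounded
in [−1, 1], scale-invariant, and undefined (flagged, not NaN) when both
terms are zero.

### Offset-decay measurement

The generator's post-bout decay is exponential with time constant
$\tau_\mathrm{off}$, so the time to fall to 10% of the offset value is
$\tau_\mathrm{off}\ln 10$ in closed form. A literal "first bin below 10% of
the time-0 value" crossing is biased early on z-scored data because the
PETH decays toward the (negative) quiet baseline, not toward zero.
`peth_decay_time()` therefore fits a single exponential
$b + (v_0 - b)e^{-t/\tau}$ to the post-alignment mean (`stats::nls` with
`SSasymp`) and reports $\hat\tau \ln(1/f)$; the naive crossing is available
as `method = "crossing"`.

## Synthetic sessions: what they emulate

The generator reproduces the two recording designs:

- **Head-fixed**: each stimulus presented exactly 5 times for 10 s with
  40-s intervals and at least 5 min between stimuli — the schedule is
  deterministic and conserved to within one sample.
- **Freely moving**: each intruder present for 10 min, investigation bouts
  with exponential gaps (mean 15 s) and lengths (mean 3 s, minimum 0.8 s),
  and, for the male intruder, an attack following an investigation bout
  with configurable probability — giving the
  investigation-followed-by-attack structure the behavior module
  classifies.

Each bout evokes a transient with probability $p_s$; the kernel rises as
$1 - e^{-(t-\mathrm{on})/\tau_r}$ ($\tau_r$ = 0.2 s) during the bout and
decays as $e^{-(t-\mathrm{off})/\tau_\mathrm{off}}$ after it. The two
class presets encode the qualitative contrast between a male-specific,
slow-decaying population and a broadly social, fast-decaying one:

| preset | amplitude (ΔF/F) | $\tau_\mathrm{off}$ | 10% return time |
|---|---|---|---|
| `sim_config_foxp2()` | male 0.15, others 0 | 12 s | 27.6 s (> 10 s) |
| `sim_config_dbx1()` | male 0.10, female 0.13, pup 0.10 | 1.2 s | 2.76 s (< 3 s) |

$\tau_\mathrm{off}$ = 1.2 s was chosen (rather than, say, 1.5 s) so that the
closed-form 10% return time of the fast class stays under the 3-s bound that
defines "fast" here; 1.5 s would put it at 3.45 s, on the wrong side of its
own definition. Sampling rate (25 Hz), noise SD (0.3 raw units on
$F_0 = 100$) and bleach amplitude (0.2 over the session) are declared
defaults, not inferred quantities — acquisition systems vary and nothing in
the analysis depends on their exact values.

Ground truth records the drift, the exact latent ΔF/F, its whole-trace
z-score (`fz_latent`), every bout's response flag, and the latent threshold
crossing time computed under the same time-0 convention the detector uses.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: correlated (pink) noise and motion artifacts,
hemodynamic or isosbestic-channel effects, transient amplitude variability
and sensor nonlinearity, behavioral label noise, and any coupling between
behavior and signal other than the implanted kernel. Tests on these
sessions validate the estimators' arithmetic and calibration, not
robustness to those artifacts.

## Behavior module conventions

Bout intervals are half-open `[onset, offset)` in seconds; frame-based
annotations convert at 25 frames/s. Grooming is folded into investigation
(per stimulus), and same-label bouts separated by less than one annotation
frame (0.04 s) coalesce — sub-frame gaps are quantization artifacts.
"Followed by attack" uses a closed interval: an attack starting within
`[offset, offset + gap_max]` (default `gap_max` = 1 s, configurable and
reported) qualifies, so at `gap_max = 0` exactly-abutting attacks still
count. Whether intervening non-attack behaviors should break the link is
genuinely open; the gap rule is the declared proxy and the brute-force
pairwise oracle in the tests pins its semantics.

## Circuit quantification choices

QC inequalities are strict ("more than 70%" fails at exactly 70%).
Excluded regions (LH, anterior MeA, AAA for rabies; LH, anterior MeA for
anterograde) are dropped *before* normalization, so fractions sum to 1 over
the analyzed regions. Negative background-subtracted intensities clamp to
zero — contralateral background can exceed signal in empty regions. The
2% input floor and the 0.2 intensity floor act on reporting only, never on
normalization; VMHvl is always reported for projections. The reporting
floor is applied to whatever table it is given — per-animal or group mean —
with group means the recommended usage. Point-to-line distances project
onto the infinite line (the optic tract is a reference line, not a
segment). The region vocabulary is an editable list; unknown names pass
through with a warning rather than failing, since atlas nomenclature
varies.

## PSC detection choices

Detection operates on the across-sweep mean (single amplitude and latency
per cell), with a 50-ms baseline ending at light onset and a 50-ms search
window (covering ~4-ms monosynaptic and >10-ms polysynaptic latencies).
The threshold is a strict, direction-aware exceedance of 1.5× baseline SD —
inward at −70 mV, outward at 0 mV — and must be sustained for ≥ 1 ms: at
20 kHz, a bare first-crossing rule would fire on single noise samples in
any 50-ms window, whereas synaptic currents last milliseconds. A zero-SD
baseline with a flat trace is non-responsive, not an error, so noiseless
fixtures behave sensibly. Amplitude is invariant to a constant
holding-current offset by construction (baseline subtraction).

The pharmacological truth table is exhaustive: ACSF-non-responsive → none;
responsive / abolished by TTX / recovered by TTX+4AP → monosynaptic;
not recovered → polysynaptic; responsive under TTX alone → flagged
inconsistent; missing pharmacology → unclassifiable.

## Problem sizes and runtime

The validation studies use sizes chosen to estimate each quantity with
useful precision on a single CPU: 10 sessions per cell class for tuning
recovery; 200 eight-animal cohorts of 4.8-min zero-amplitude sessions for
null calibration (7,200 bin-level tests); 1,000 random p-vectors for the BH
oracle; ~215-bout sessions for the 32% / 55% response-rate recovery
(3 binomial SEs ≈ ±9.5 points at n ≈ 215); and latencies 1–20 ms at both
holding potentials for the PSC suite. The full test suite runs in about a
minute; `scripts/acceptance.R` in under a minute.

## Known limitations

- No isosbestic regression or motion correction; traces are assumed
  artifact-free apart from bleaching.
- The baseline estimator assumes transients are positive-going; inhibitory
  (negative) transients would be absorbed into the envelope.
- Pointwise PETH inference treats bins as the multiple-testing family;
  neighboring bins are correlated, which BH tolerates but does not exploit.
- The decay-time fit assumes a single-exponential return; multi-phasic
  decays would need a different model.
- Circuit metrics operate on curated per-region tables; no image
  segmentation or atlas registration is attempted.
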