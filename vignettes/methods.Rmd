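---
title: "Peri-ictal EEG spectra, entropy and coherence networks: methods and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peri-ictal EEG spectra, entropy and coherence networks: methods and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`seiznet` implements a complete pre- versus post-seizure scalp-EEG analysis:
preprocessing, Welch band power, fuzzy entropy, magnitude-squared coherence
networks with weighted graph metrics, channel-/edge-wise paired statistics
with FDR control, and the correlation of network metrics with consecutive
seizure number. Because clinical peri-ictal recordings are rarely shareable,
the package treats a synthetic EEG generator with planted ground truth as a
first-class component: every claim the pipeline makes about real data is
backed by a recovery experiment on data whose truth is known.

This vignette records the scientific and numerical choices behind each
stage, what the synthetic generator does and does not emulate, and the known
limitations.

## The analysis pipeline

Recordings are 16-channel scalp EEG in the 10-20 montage (Fp1, Fp2, F3, F4,
F7, F8, C3, C4, P3, P4, O1, O2, T3, T4, T5, T6) sampled at 256 Hz in
microvolts, with seizure onset/offset annotations. Around each annotated
seizure, a 10-minute window immediately before onset (`[onset - 600, onset)`)
and after offset (`(offset, offset + 600]`) are extracted; intervals are
half-open in seconds so epoch counts are unambiguous, and a configurable
`guard_s` (default 0) can insert a gap at the seizure boundary.

Preprocessing is a fixed chain:

1. **Common-average re-reference.** Every sample is centred across channels.
   Idempotent; requires at least two channels.
2. **Band-pass 1-45 Hz.** 4th-order Butterworth applied forward-backward, so
   the net filter is zero-phase (`|H(ω)|²` magnitude, no group delay) and
   epoch alignment is preserved. The forward-backward pass is evaluated in
   the frequency domain on odd-reflection-padded signals (3 s per end),
   vectorized across channels; this matches per-channel `filtfilt` to about
   1% away from the boundaries and is what makes the 2000-replicate null
   calibration below affordable.
3. **Segmentation into 6-s epochs,** consecutive and non-overlapping from
   the first sample; a trailing remainder is discarded (600 s yields exactly
   100 epochs of 1536 samples).
4. **Amplitude-threshold artifact rejection.** An epoch is excluded iff any
   sample on any channel exceeds 80 µV in absolute value, using a strict
   `>` (the boundary value is retained; an `inclusive` switch is provided
   since the convention is ambiguous). Whether rejection should be
   any-channel or per-channel is a genuine open choice; any-channel is used
   because a high-amplitude excursion on one electrode usually reflects a
   non-neural event contaminating the whole epoch.

### Spectra and band power

PSDs use Welch's method: 2-s Hann windows with 50% overlap inside each
retained epoch, mean-removed per window, averaged across windows and
epochs. 2-s windows give 0.5 Hz resolution — enough to resolve the delta
band — and five averages per 6-s epoch. The scaling is Parseval-consistent
(the one-sided PSD integrates to the signal variance up to taper
correction). Band powers integrate the PSD with the trapezoid rule across
each band's grid points, band edges inclusive, so the five bands — delta
1-4, theta 4-8, alpha 8-13, beta 13-30, low gamma 30-45 Hz, the
conventional clinical edges consistent with the 1-45 Hz filter — sum
exactly to the total 1-45 Hz power. Paired statistics operate on log10
band power (variance stabilization); raw power is exported alongside.
Absolute power is the default; relative power is available behind a flag.

### Fuzzy entropy

Fuzzy entropy of a series x is computed from baseline-removed templates of
length m and m+1: template similarity is the smooth membership
`exp(-(d / r_abs)^n)` of the Chebyshev distance d, with `r_abs = r · SD(x)`;
φ^m is the mean similarity over distinct template pairs (self-matches
excluded), and the entropy is `ln φ^m − ln φ^(m+1)` (nats). Defaults
m = 2, r = 0.2, n = 2 follow the dominant convention in the EEG
fuzzy-entropy literature; all three are exposed. Baseline removal and the
SD-relative tolerance make the measure invariant to offsets and positive
rescaling. A constant signal returns 0 with a warning rather than an error,
so an all-flat epoch cannot abort a batch run. The O(N²) pairwise loop is
compiled (Rcpp); a literal R double-loop oracle in the test suite pins the
implementation to 1e-12 relative on hundreds of random signals.

Band-limited entropy (the pipeline's default is the delta band) filters
each epoch with the same zero-phase band-pass and then **decimates to
roughly four times the band's upper edge** (delta: 256 Hz → 16 Hz). This
step matters: a 1-4 Hz signal at 256 Hz is so oversampled that lag-1
template distances collapse and fuzzy entropy saturates near zero,
insensitive to in-band structure. No anti-aliasing is needed because the
signal is already band-limited. Broadband entropy skips both steps.

### Coherence networks

Connectivity is magnitude-squared coherence,
`C(f) = |S_xy(f)|² / (S_xx(f) S_yy(f))`, with cross- and auto-spectra
Welch-averaged with the same windows as the PSD. Band-level edges are the
mean of C(f) over the bins inside `[low, high)` — the mean rather than the
peak because it is the variance-minimizing choice and no alternative is
standard. The per-state network pools windows across all retained epochs
of that state; per-epoch matrices (five windows each) are also produced as
the pairing unit for edge-wise statistics. Coherence from a single
averaging segment is identically 1, so at least two segments are enforced;
with L segments the coherence of independent signals has expectation ≈ 1/L,
a bias that is substantial per epoch (L = 5 → 0.2) but cancels in paired
pre/post comparisons. The diagonal is set to 0 so graph metrics never
traverse self-loops.

### Graph metrics

Networks are full weighted matrices — no density threshold is applied,
since none is standard for coherence networks (a proportional threshold
exists for sensitivity analysis only). Edge lengths for shortest paths are
`1/w` (the standard convention for similarity weights; `1-w` behind a
flag); the characteristic path length (CPL) is the mean shortest weighted
path over ordered node pairs. A disconnected graph errors by default, or
returns the harmonic-mean efficiency form when requested, labeled as such.

The weighted clustering coefficient is shipped in two variants that differ
in the per-node normalization of the triangle intensity
`Σ_{j,h} (w_ij w_ih w_jh)^{1/3}`:

* **printed** — denominator `s_i (s_i − 1)` with `s_i` the node *strength*
  (sum of weights). This form is the headline variant. It is not invariant
  to uniform weight scaling, and a node with strength ≤ 1 has a
  non-positive denominator; such nodes contribute 0 with a warning.
* **standard** — the conventional weighted form with denominator
  `k_i (k_i − 1)`, `k_i` the count of nonzero edges.

Both equal 1 on a complete unit-weight graph, and both are pinned to a
literal triple-loop oracle. Whether the strength-based denominator is a
typo for the degree-based one cannot be settled from the formula alone, so
neither is silently preferred: every output table reports both. One
consequence matters for validation: on the synthetic networks below, node
strengths never reach 1 (see the feasibility bound), so the printed variant
degenerates to 0 there and trend recovery is assessed on the standard
variant. On real scalp-EEG coherence networks, where mean edge weights of
0.2-0.5 give strengths of 3-7, the printed variant is well-defined.

### Statistics

Paired two-sided t-tests compare states per channel (log10 band power; raw
p < 0.05 to mirror the band-power analysis), per channel for delta-band
fuzzy entropy (Benjamini-Hochberg FDR at 0.01), and per edge (120 pairs for
16 channels; raw p < 0.05 with FDR-adjusted values co-reported), with the
sign of (post − pre) recorded so findings are directional
(enhanced/weakened, increased/decreased). "FDR" is implemented as
Benjamini-Hochberg step-up — the default meaning of the abbreviation. The
pairing unit is the epoch index within a pre/post pair by default, with a
subject-level mode for group designs; neither is privileged, since the
sampling unit of the original group analyses is genuinely ambiguous. The
seizure-number analysis orders segments 1-pre, 1-post, ..., k-post and
reports the Pearson correlation (matching the linear regressions such
figures draw) between metric value and segment rank, with a two-sided p.

## The synthetic generator

Each channel is a sum over the five bands of band-limited sources plus
white measurement noise. Per band, a channel's source mixes:

* a **broadband component**: Gaussian noise confined to the band by the
  squared magnitude response of the 4th-order Butterworth band-pass
  (i.e. the same forward-backward filter as the pipeline). Sources are
  drawn directly in the frequency domain — the DFT of iid Gaussian noise
  is exactly iid complex Gaussian, so sampling complex Gaussians on the
  filter support realizes the same process as time-domain filtering at a
  fraction of the cost — and normalized to unit sample variance by
  Parseval.
* a **rhythm component**: a Gaussian spectral line at the band centre with
  σ = bandwidth/80 (delta: 0.0375 Hz). The two are mixed in power ratio
  `1 : q` with q = 1 by default.

The rhythm width is a deliberate compromise. Fuzzy entropy of a
band-filtered signal responds to spectral concentration *within* the band,
not to the white-noise floor (which band-filtering removes); a
near-sinusoidal rhythm is what makes the complexity handle effective. But
the narrower the line, the longer its phase coherence time (~4 s at this
σ), and two independent near-sinusoids at the same frequency look coherent
over windows shorter than that. At σ = bandwidth/80 the pooled 600-s
coherence of uncoupled channels stays below 0.03 — an order of magnitude
under the recovery tolerance — while the entropy handle recovers planted
complexity shifts reliably.

**Coupling.** Pairwise coupling is planted by shared sources: channel i's
band signal is `a_i u_i + Σ_j b_ij s_ij` with unit-variance sources of
identical spectrum and `a_i² + Σ_j b_ij² = 1`. With band-centre source PSD
S_u and white-noise PSD S_n = noise_sd²/(fs/2), writing
ρ_i = S_n/(P_i S_u), the analytic magnitude-squared coherence of pair
(i, j) at band centre is `b_ij⁴ / ((1+ρ_i)(1+ρ_j))`; inverting gives
`b_ij² = sqrt(κ_ij (1+ρ_i)(1+ρ_j))` for target coupling κ. Requests that
need `b_ij² > 1`, or a channel whose shared weights exceed unit power, fail
with the offending pair named. The latter bound is worth noting:
`Σ_j sqrt(κ_ij) < 1` per channel, so dense strongly-coupled graphs are
infeasible under shared-source mixing — which is why the seizure-series
study uses a two-neighbour ring (adjacent κ = 0.09, next-adjacent 0.03)
rather than a dense network, and why node strengths stay below 1.

**Planted effects.** For segment order t (1-pre = 1, ..., k-post = 2k), the
applied coupling is `κ + edge_shifts · (I(post) + seizure_trend · (t−1))`;
the post state additionally scales delta variance by `delta_power_ratio`
per channel and the broadband-to-rhythm ratio by `1 + entropy_shift` per
channel (negative shifts concentrate power on the rhythm and lower fuzzy
entropy). Setting all three to null makes pre and post exchangeable.
Artifacts are planted as three 4 Hz square cycles plus a ramp of stated
amplitude (> 80 µV required) on one random channel of each selected 6-s
window, centred so zero-phase filtering cannot leak them into neighbours; a
burst was chosen over a single long plateau because the 1 Hz high-pass
halves a plateau's amplitude but passes the burst at ~1.4x, making planted
windows reliably, and only, the rejected ones. Generation is a pure
function of (config, state, seizure index): identical inputs give
bit-identical recordings.

**Default study conditions.** 16 channels, 256 Hz, 600 s per segment; band
variances delta 50, theta 25, alpha 30, beta 15, low gamma 5 µV² (a
delta-dominant spectrum with total SD ≈ 12 µV, so the ±80 µV threshold
sits at ≈ 6.5 SD and clean data are essentially never rejected);
measurement noise 5 µV. Effect sizes for recovery experiments: 2x delta
power on six designated electrodes, entropy shift −0.9 on the same,
coupling shifts ±0.25 on three weakened (0.40 → 0.15) and three enhanced
(0.10 → 0.35) pairs, and a seizure-series degradation removing 9.5% of the
planted ring coupling per segment step. These are strong but
physiologically plausible contrasts — peri-ictal delta-power changes of
this order are routinely reported — and they were fixed from pilot runs on
seeds disjoint from the test seeds before the validation experiments were
frozen.

**What the generator does not emulate.** Ictal waveform morphology
(spikes, sharp waves, evolving rhythms), 1/f broadband background beyond
the five flat-band variances (a configurable spectral shape is left open),
volume conduction and reference-field spread, non-stationarity within a
segment, and realistic artifact morphologies (ocular, muscle). Passing the
recovery experiments therefore demonstrates that the estimators and tests
recover what they claim under a controlled band-structured Gaussian
regime — not that any specific clinical effect will be detectable in real
recordings.

## Validation design and problem sizes

The test suite's end-to-end experiments use these scales, chosen so the
whole suite runs comfortably on one CPU:

* coherence calibration: κ ∈ {0.1, 0.3, 0.5, 0.7, 0.9} on a 2-channel
  600-s recording (100 epochs), 20 seeds per κ; recovered within ±0.1 and
  strictly monotone.
* null calibration of the channel-wise band-power test: 2000 replicate
  pre/post null pairs (8 channels, 24 s each), per-channel rejection ≤ 7%
  at α = 5%.
* channel-effect recovery: 20 seeds, 600-s states; the six planted
  channels — and only those — detected at FDR 0.05 with the correct
  (post > pre) direction in ≥ 90% of seeds.
* edge recovery: 20 seeds; all six planted coupling shifts recovered with
  correct signs in ≥ 90% of seeds, false-positive edges ≤ 6 on average.
* trend recovery: 40 seeds of a four-seizure series (120-s segments);
  r(CPL, order) > 0 and r(CC, order) < 0 in ≥ 95% of seeds; 40 null
  series (60 s) with |r| < 0.7 in ≥ 90% per metric.

Two design notes. First, the recovery experiments omit the common-average
re-reference: with n independent channels the average reference
redistributes 1/n of any planted per-channel or per-pair effect into every
other channel (and for n = 2 it forces perfect anticorrelation), which
confounds exact-recovery checks of the *statistics*; the full fixed chain
including re-referencing is exercised by the null-calibration and
determinism experiments, and a montage-sensitivity analysis on real data
should treat the reference as a modelling choice. Second, coherence-based
experiments run on raw segmented epochs: magnitude-squared coherence is
exactly invariant to applying the same linear filter to both channels, so
the band-pass is a mathematical no-op there.

## Numerical choices and degenerate inputs

* Welch segments are mean-removed per window; one-sided scaling doubles
  all bins except DC and Nyquist.
* Band-power integration includes both edge grid points (trapezoid), so
  contiguous bands tile the spectrum additively; band membership for
  coherence averaging is half-open `[low, high)`.
* Coherence values are clipped to [0, 1] against roundoff.
* The EDF writer quantizes to 16-bit integers over a symmetric physical
  range covering the data (quantization error ≤ range/32767); recordings
  must span an integer number of seconds (EDF records are 1 s).
* Zero-variance paired differences error (a t-test is undefined); an
  all-zero difference vector returns t = 0, p = 1.
* Constant metric series in the trend analysis yield NA inside the
  pipeline report rather than aborting the run.
* All randomness is seed-derived; the generator saves and restores the
  ambient RNG state, so calling it does not perturb a caller's stream.

## Limitations

* Coherence is sensitive to volume conduction and the reference montage;
  imaginary coherency, PLV, or wPLI are deliberately out of scope.
* The printed clustering variant is undefined for node strengths ≤ 1 and
  is reported as 0 there; on sparse or weakly coupled networks only the
  standard variant is informative.
* Per-epoch coherence (5 windows) carries a 0.2 bias; only paired
  contrasts of it are meaningful, never its absolute level.
* The EDF reader supports continuous 16-bit EDF with a single sampling
  rate; EDF+ annotations, discontinuous records and mixed rates are not
  parsed (annotations travel in a JSON sidecar instead).
* Group-level inference across subjects (mixed models, cluster-based
  permutation) is out of scope; the pairing unit is epochs within one
  subject's pre/post pair, or subject means supplied by the caller.
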