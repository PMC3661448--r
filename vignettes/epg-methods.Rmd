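---
title: "EPG simulation, detection and phenotype sorting: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EPG simulation, detection and phenotype sorting: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the generative
model behind the synthetic electropharyngeogram (EPG) traces, the signal
processing and event detection that recover pump events from them, the
summary statistics and the classification rule, and the design decisions
taken where the published description left the design open. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## 1. The signal and the measurement problem

Each pharyngeal pump appears in an extracellular recording at the worm's
mouth as a stereotyped complex: a small positive **e** spike (pacemaker
neurone MC) leading the large positive **E** spike (muscle excitation), a
plateau carrying zero or more small negative **P** waves (inhibitory M3
motor neurons), then the large negative **R** spike (corpus/isthmus
repolarisation) trailed by a small **r** spike (terminal bulb). Seven
per-recording parameters summarise a trace: peak-to-peak amplitude
$\overline{a_E - a_R}$, pump frequency $n/T$, pump duration
$\overline{t_R - t_E}$ (peak E to peak R), R-to-next-E interval, P waves
per pump, e amplitude, and the shape ratio $\overline{|a_R|/a_E}$.

The phenotypes the package targets, in the units the tables print:

| preset | freq (s⁻¹) | duration (s) | P/pump | amp (mV) | e (mV) | R/E |
|---|---|---|---|---|---|---|
| wild-type basal, chip | 0.075 | 0.116 | 1.788 | 4.410 | 0.257 | 1.222 |
| wild-type + 5-HT, chip | 3.467 | 0.101 | 0.126 | 8.370 | 1.753 | 1.143 |
| *eat-4*, chip | 0.090 | 0.172 | 0.103 | (4.410)* | 0.376 | 1.491 |

\* no amplitude is published for *eat-4*; the preset reuses the wild-type
on-chip value (marked synthetic in the preset file).

## 2. The generative model

`generate_trace()` is phenomenological, not biophysical: it composes
transient bumps on a sampled grid. Mechanistic membrane or circuit
dynamics are out of scope.

**Hierarchy.** A worm draws six lognormal multipliers (unit mean,
CV = `worm_cv`) applied to the preset means — between-worm spread. Within
a worm, per-pump duration and amplitude draw further lognormal multipliers
(`dur_cv`, `amp_pp_cv`, both default 0.1), and the P count per pump is
Poisson with intensity `p_rate`, truncated to the number of waves that
physically fit the plateau. Default `worm_cv = 0.10`: the published
standard errors imply between-worm CVs from ~0.03 (amplitude) to ~0.9
(P count under serotonin), but the preset schema carries a single spread
parameter, so a representative mid-range value was fixed once.

**Pump timing.** E-to-E intervals follow a *refractory renewal process*
(a biologically natural refractoriness: the pharynx cannot re-excite
while still relaxing):
a hard minimum separation (the previous pump's rendered extent plus a
5 ms silent gap) plus a gamma-distributed excess, with the total mean held
at exactly $1/f$. The first implementation drew plain gamma intervals
(CV 0.3) and thinned overlapping pumps, but at serotonin-stimulated rates
(mean interval 0.29 s vs. a ~0.18 s pump footprint) thinning discards
~10 % of pumps and the realized rate misses its target; the refractory
form keeps pumps disjoint *and* converges to the preset frequency. The
cost is a smaller effective interval CV at high rates, which no target
quantity depends on.

**Waveform.** Transients are Gaussian bumps (FWHM = the kernel width,
truncated at ±4 sd so inter-pump baseline is exactly zero in noise-free
mode); a biexponential shape is available. Kernel defaults — e leads E by
25 ms; widths 8–10 ms; r lags R by 20 ms; r = 0.4·|R| — make all five
phases resolvable at the default 2 kHz sampling rate (the acquisition
rate is not published; EPG transients last 10–100 ms, so 2 kHz gives
≥ 16 samples per transient). The amplitude split is
$a_E = \mathrm{amp}/(1+\rho)$, $a_R = -\rho\,a_E$ with $\rho$ the R/E
ratio. **P amplitude is not published anywhere**; the kernel default
`p_rel_amp = 0.5` (half the E spike) places P between the small e and the
large R, consistent with the published waveform morphology. P waves are
placed uniformly in the plateau, clear of the E and R transients by one
E-width plus one P-width and mutually separated by ≥ 2 P-widths.

**Interference.** Baseline drift is a sum of three sinusoids with random
frequencies in [0.02, 0.3] Hz and total amplitude ≤ 20 % of the
peak-to-peak amplitude — a stand-in for residual worm movement, placed
entirely below the 0.5 Hz high-pass cutoff so preprocessing can remove
it. Noise is white Gaussian with $\sigma = \mathrm{amp}/\mathrm{snr}$.

**Noise calibration (`snr = 50`).** The published device floor is
"SNR larger than 8". Taken literally as $\mathrm{amp_{pp}}/\sigma = 8$,
basal noise would be $\sigma = 0.55$ mV — *twice* the printed basal e
amplitude (0.257 mV), making the e spike undetectable by any method; yet
e was measured (manually) on those recordings. The printed floor is
therefore a conservative bound, presumably not a σ-based definition, and
the default calibration is $\mathrm{amp_{pp}}/\sigma = 50$
(σ ≈ 0.09 mV basal), at which e sits ~3σ above the matched-channel noise
— about the weakest signal a human scorer would accept. The SNR-floor
acceptance criterion (estimated SNR ≥ 8) passes a fortiori, and detector
robustness is tested separately at snr = 8.

**Condition schedules.** Effects multiply frequency, duration, P
intensity and excitation amplitude inside labelled intervals, ramping as
$1 + (m-1)(1 - e^{-(t-t_0-\ell)/\tau})$. Defaults: serotonin wash-in
latency ℓ = 300 s and τ = 300 s (≈ 95 % of full effect 15 min after
application, matching the published response time); ethanol ℓ = 0 with
half-time 90 s (published: under 2 min); illumination as a step active
only during `light_on` intervals. Multiplier magnitudes for ethanol and
light are illustrative defaults — the source figures are not tabulated.

**Tail-first worms.** Wrong-orientation recordings are modelled as
pump-rate-matched *monophasic* positive blips at ~22 % of the head
amplitude with no e/P/R/r structure, which is what the orientation gate
must reject.

## 3. Drift removal

`highpass()` implements a zero-phase (forward–backward) Bessel high-pass.
The published setting — "0.5 Hz −30 dB cut-off" — is interpreted
literally: the designed single-pass gain at 0.5 Hz is −30 dB. This is
*not* the conventional −3 dB corner (that falls near 1.4 Hz here); both
numbers are `filter_spec()` fields, so the conventional reading
(`attenuation_db = 3`) is one configuration away. Whether the printed
"−30 dB" is a typo for −3 dB is undecidable from the text; it is a config
default, not a resolved question. Order 4 (unstated in the source) is the
lowest order reaching 30 dB at 0.5 Hz with a well-conditioned design at
2 kHz.

The design path: reverse-Bessel-polynomial poles (delay-normalised),
lowpass→highpass transform with the corner chosen by root-finding so the
analog gain at the cutoff equals the prescribed attenuation, then a
prewarped bilinear transform to second-order sections. Application
subtracts the DC mean exactly (DC is in the stopband; this removes the
step transient), pads both ends with odd-symmetric reflections, and runs
the cascade forward and backward. Bessel maximises group-delay flatness,
so transient shapes pass essentially undistorted; the zero-phase
application means event *times* are unshifted.

Zero-phase high-passing of a transient with net area leaves a shallow,
broad compensation lobe around it. Pump complexes have net negative area,
so the local baseline under each pump is lifted by a few percent of the
spike height and a small undershoot trails the E spike. `highpass()`
therefore applies first-order *transient-distortion compensation* by
default: writing the zero-phase filter as $1 - L$ (with $L$ the
complementary low-pass that carries the drift), the returned signal is
$2y - (1-L)y = (1-L^2)x$, which cancels the lift to second order while
stopband leakage merely doubles in amplitude (−47 dB → −41 dB at
0.3 Hz single-pass — still far below anything the detector can see).
Without compensation, recovered peak-to-peak amplitudes were biased
−3 to −6 % and R/E ratios −5 to −9 %. Residual artifacts (now an order
of magnitude smaller) are further neutralised by detector choices below.

## 4. Event detection

All thresholds are multiples of a robust noise σ (1.4826 × MAD), never
absolute millivolts, so the same configuration serves adult-scale and
amplitude-scaled (e.g. larval) recordings.

1. **Channels.** Candidates are located on boxcar-smoothed copies of the
   baseline-subtracted signal: 3 ms for spikes (attenuates a 10 ms
   transient ~2 % while suppressing single-sample noise extrema), 6 ms
   for P waves, the latter further detrended by a 41 ms running median so
   the post-E undershoot lobe (broad) is flattened while an 8 ms P dip
   (narrow) is not.
2. **Pairing.** E candidates (maxima > k·σ, default k = 5) pair with the
   deepest trough before the next major E candidate within 0.5 s. The
   naive "nearest following trough" rule fails whenever P waves exceed
   the spike threshold — true for any recording with SNR ≳ 12 — because
   the nearest trough after E is then a P wave, not R.
3. **Self-calibrating second pass.** A coarse pass estimates the median
   E height and R depth from the dominant amplitude cluster; the
   refinement pass additionally requires candidates to reach half those
   heights. In σ units alone, a 5σ threshold on a 10-minute recording is
   crossed by dozens of noise maxima (each able to seed a false pump or
   truncate a pairing window); in relative-amplitude units the P and r
   troughs (≤ ~half an R) can never be mistaken for R. Conflicting pairs
   are resolved greedily by combined spike magnitude, with a 50 ms
   minimum inter-pump separation. All σ estimates are refined between
   the passes on samples away from the detected spikes: at 3.5 pumps/s
   the transients inflate a whole-trace MAD ~25 %, which would silently
   raise every nominal σ multiple (losing low-amplitude pumps near the
   SNR floor).
4. **Labelling.** Per pump: e is the largest local maximum above
   `p_threshold_k`·σ (default 4) in a 5–60 ms window before E, located
   on the e-width-matched channel; r the deepest local minimum in a
   5–120 ms window after R; P waves are local minima in the open E–R
   plateau beyond 4σ on the detrended channel, clear of R by 10 ms,
   merged when closer than 4 ms.
5. **P specificity gates.** Within 40 ms after E a P candidate must clear
   the threshold *plus* 6 % of the E height (the measured relative depth
   of the filter's undershoot lobe); dips broader than 20 ms at half
   depth are rejected (a genuine P is ~8 ms FWHM); and dips shallower
   than 0.25 × the recording's 90th-percentile P depth are dropped. The
   last gate self-deactivates at low SNR (the floor falls below the 4σ
   threshold) and is what keeps the false-P rate near zero on *eat-4*
   recordings, where true P waves are so rare (~0.1/pump) that even a few
   threshold-grazing noise dips would double the count. Cost: the
   occasional closely spaced P pair (a few percent in dense-P basal
   recordings) is dropped.
6. **Amplitudes.** E/R/P/r amplitudes are read from the *raw* filtered
   trace by parabolic interpolation at the located index (no smoothing
   attenuation), relative to the pump's own plateau median
   (P neighbourhoods masked) — the most local reference available and
   the one that tracks any residual baseline lift. Measuring amplitudes
   at smoothed extrema against a global running median, the obvious
   first implementation, biased $|a_R|$ by ~10 %. The e amplitude is
   special: at basal e/noise ratios, per-pump "largest local maximum"
   measurement carries a +5 % pick-the-max selection bias, enough to
   break the e recovery band. e is therefore re-measured at the
   recording's *median e-to-E lag* (the e spike is stereotyped relative
   to E) by a plain 5-sample average — no per-pump location choice, no
   selection bias — against a baseline interpolated linearly between the
   pre-pump flank and the plateau medians, the two measured baseline
   segments flanking the e position. If real recordings jitter the
   e-to-E lag by more than ~1.5 ms, this under-estimates e slightly; the
   trade-off is documented here deliberately.

**Orientation gate.** A recording is `tail_or_bad` if fewer than 3 pumps
are detected, the median per-pump peak-to-peak is below a quarter of the
reference head amplitude (default 4.410 mV), or — with ≥ 10 pumps —
fewer than 5 % of pumps carry any e/P/r detail.

## 5. Parameters, time courses, statistics

`compute_parameters()` implements the definitions in §1. Conventions:
`e_amp` averages only pumps with a detected e (no zero-imputation — the
source measured e manually on visible waveforms); R-to-E gaps spanning a
condition-schedule boundary are excluded from `re_interval` (wash-in
transients would bias it); the worm, never the pump, is the statistical
unit, and `compare_groups()` is a Welch t-test on per-worm values.
`frequency_timecourse()` bins pumps by E time; `epoch_summary()` averages
bins fully inside each schedule interval, supporting the
before/during/after illumination comparisons and drug wash-in curves.

## 6. Classification and the screen

`classify()` applies one-sided bounds with strict inequalities, exactly
as published: mutant iff duration > 0.1445 s **and** P/pump < 0.169
(default `rule = "conjunction"`). The wild-type definition ("within 3σ on
both metrics") logically implies that *either* excursion should flag a
mutant; `rule = "disjunction"` is first-class, and every report names the
rule used. Thresholds may be given explicitly (default — the published
constants, whose derivation from the validation worms is not recoverable:
the printed standard errors do not reproduce 0.1445) or fitted from
wild-type worms via `fit_reference()`. Worms with fewer than 5 pumps are
unclassifiable (P/pump is too granular below that); tail-first worms are
rejected, never classified. Only the upper duration bound and lower P
bound decide — the direction of the *eat-4* phenotype; other metrics ride
along in the verdict for reporting.

## 7. What a green test establishes — and what it does not

The simulator emulates: the published phenotype means; between-worm and
within-worm lognormal variability; Poisson P counts; sub-0.3 Hz drift;
white noise at a stated amplitude ratio; condition schedules with
published latencies. It does **not** emulate: electrode/seal artifacts,
movement transients faster than 0.3 Hz, non-Gaussian or correlated noise,
amplitude drift within a recording, superposition of e on the E rising
edge at extreme rates (flagged `missing_e`, not deconvolved — resolving
it is explicitly left open by the source), or any biophysics. Green
recovery tests therefore establish that *the pipeline is unbiased for the
stated generative world at the stated scales* — not that it would be
unbiased on real recordings.

**The screen-reproducibility criterion is expected to fail, and that is a
finding.** The acceptance criterion asks the 7 + 3 spiked screen to sort
with zero errors in ≥ 95 % of replicates. Under the published means and
any realistic between-worm spread this is not attainable with the
published conjunction rule: an *eat-4* worm at 0.090 pumps/s yields only
~27 pumps in a 5-minute screen, so its observed P/pump is granular in
steps of ~0.04 and exceeds the 0.169 threshold by chance alone in ~15 %
of worms (P(≥ 5 P waves | mean 2.8) ≈ 0.15), and its mean duration falls
below 0.1445 s in several percent of worms at `worm_cv = 0.10`
(z ≈ 1.7). Three spiked mutants must all be caught, so the per-replicate
success probability is roughly 0.8³ ≈ 0.5–0.6. The single published
zero-error run of 10 worms is entirely consistent with that probability;
demanding it in 95 of 100 replicates is not. The criterion is implemented
faithfully and left red rather than weakened; the generator was not
re-tuned to force it green.

## 8. Numerical choices and degenerate inputs

Sampling-rate round trips are exact because the rate is carried in the
file header (re-deriving it from printed time stamps loses the last
ulp). Filter padding is ~3/f_c seconds of odd reflection; DC removal is
exact by mean subtraction. In noise-free mode MAD = 0, thresholds
degenerate to zero, and detection reduces to exact extremum matching —
the basis of the oracle tests. Empty traces, zero-frequency presets,
empty event tables and single-pump recordings all return well-formed
empty/missing records rather than errors; per-worm failures inside a
cohort screen become `unclassifiable` verdicts and never abort the run.
Seeds: every simulation entry point takes one; cohort and CLI runs derive
per-worm sub-seeds below 2³¹ from it, and the RNG state of the caller is
restored afterwards.

## 9. Known limitations

* The detector's P-specificity gates trade a few percent of closely
  spaced P waves for near-zero false positives; at the published SNR
  floor (snr = 8) the net P-count bias is several percent and seed runs
  range to ~±10 %.
* The single `worm_cv` cannot reproduce the metric-specific between-worm
  spreads the published standard errors imply.
* Amplitude measurements carry a residual −2 to −4 % bias from the
  aggressive −30 dB/0.5 Hz zero-phase filter (transient area removal);
  within recovery tolerances, but visible.
* `estimate_snr()` requires detectable pumps below snr ≈ 5 only if given
  an external event table; auto-detection at such noise levels fails by
  design (the spike threshold exceeds the E height).
* The CLI is deliberately thin; plots are optional artifacts and never
  inputs to computation.
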