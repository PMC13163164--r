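---
title: "Phase-dependent auditory stimulation analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-dependent auditory stimulation analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(clasphase)
```

## The scientific question

Auditory tones delivered during deep non-rapid-eye-movement (NREM) sleep can
enhance slow oscillations (SOs, the dominant ~0.8 Hz EEG rhythm of deep
sleep) and slow-wave activity (SWA, 0.5–4 Hz spectral power), but only when
they arrive at favourable phases of the ongoing oscillations. Beyond the
cortical SO phase, the oscillatory components of instantaneous heart rate —
the low-frequency (LF, 0.04–0.15 Hz) and high-frequency (HF, 0.15–0.4 Hz)
bands — index autonomic state and carry complementary timing information.
`clasphase` implements the complete post-hoc analysis of such an experiment:
given one EEG channel, one ECG channel, a 30-s-epoch hypnogram, arousal
annotations and a tone-onset list, it quantifies how the tone-evoked
response depends on the instantaneous phases of EEG-SO, HR-LF and HR-HF, and
compares binary upstate/downstate phase-locking strategies, unimodal and
combined.

Because the study's recordings are not redistributable, the package ships a
synthetic polysomnography generator whose tone-evoked responses follow a
*known* phase law. Every downstream stage is validated against that ground
truth.

## Signal processing conventions

All filters are fourth-order Butterworth designs applied forward and
backward (`signal::filtfilt`), so the effective filter is zero-phase with a
squared magnitude response. One numerical caveat drives an implementation
choice: an order-4 band-*pass* in transfer-function form is ill-conditioned
when the lower band edge is a tiny fraction of Nyquist (for 0.5–4 Hz at
256 Hz we measured a 9% passband error). `zero_phase_bandpass()` therefore
cascades an order-4 high-pass and an order-4 low-pass when
`low_hz/(fs/2) < 0.005` and uses the direct band-pass otherwise (the HR
bands on the 10 Hz grid, the 11–16 Hz spindle band). Both are zero-phase;
passband gain is within 1% at band centre either way.

Artifacts are flagged per 8-s segment: any sample beyond ±1500 μV, or a
segment whose standard deviation is an extreme outlier among segments. The
outlier rule is implemented as a leave-one-out z-score greater than 10; a
self-inclusive z-score of a single segment among *n* can never exceed
(n−1)/√n, so the leave-one-out form is the only reading under which a
lone pathological segment is flaggable at z > 10.

Slow oscillations are segments between consecutive downward zero crossings
of the 0.5–4 Hz signal with trough < −80 μV (strict), peak-to-peak
> 140 μV (strict) and duration within 0.25–2.5 s (inclusive). Spindles are
supra-threshold runs of the 0.2-s RMS envelope of the 11–16 Hz signal,
thresholded at the 88.86th percentile of artifact-free N2/N3 samples,
lasting 0.3–3 s with at least five full oscillations and a unimodal Morlet
spectrum: wavelet centre frequencies 10–20 Hz in 0.5 Hz steps, six-cycle
width, exactly one local maximum inside 11–16 Hz with all power above 16 Hz
strictly below it. The RMS window smears the envelope outward by half a
window on each side, so event bounds are trimmed by that known support
before the duration rule is applied; without the trim, measured durations
are biased long by the window length.

Instantaneous phase is the Hilbert analytic-signal angle plus 90°, wrapped
to [−180°, 180°), so that −90° marks the trough, 0° the
negative-to-positive zero crossing and +90° the peak. The transform is
computed on the full trace with 10 s of reflection padding; we do not split
at artifact runs because the ±10 s artifact exclusion already removes
affected trials and extra splits would introduce their own edge transients.
Since the upstate/downstate boundary at 0° cannot belong to both halves,
0° is assigned to the upstate (half-open intervals).

Instantaneous heart rate assigns 60/RR to each RR interval's *midpoint*
before cubic-spline interpolation onto the 10 Hz grid: an interval's 60/RR
is its mean rate, which a slowly varying modulation attains mid-interval.
Anchoring at the end beat instead would lag the true rate by half an
interval — about 45° of phase at 0.25 Hz — and systematically bias the HF
phase estimates. RR intervals outside 0.25–3 s or beyond 10 standard
deviations of the recording mean are excluded; the first and last 30 s of
the LF/HF components are flagged unreliable and excluded from phase
queries.

## Trial construction

STIM trials are tones in N2/N3 whose ±10 s window is wholly within N2/N3,
artifact-free and arousal-free. UNSTIM windows are the midpoints of maximal
tone-free intervals of at least 20 s meeting the same criteria — one window
per interval, since a midpoint is only defined once per interval; this also
guarantees the response window never extends past the interval. Both trial
types are retained only if a detected SO trough falls within 2.5 s after
the (hypothetical) onset; 2.5 s is the upper SO duration bound and the
latency is not otherwise constrained by the design. Responses per trial:
the attached SO's peak-to-peak amplitude; normalized SWA over
[onset, onset+8 s] (one Welch estimate: 4-s Hann segments, 50% overlap,
interpolated to a 0.1 Hz grid, normalized by the subject's mean 0–20 Hz
power over stimulated windows); a stimulus-dependent-spindle flag (a
spindle initiating after the SO trough, before onset+10 s); and the HR
peak-to-peak excursion over [onset, onset+10 s].

## Inference

Responses are mean-centered within subject, separately for STIM and
UNSTIM. The separation matters: centering the pooled responses would leave
any constant STIM−UNSTIM offset in every phase bin, and a global
stimulation effect would then masquerade as phase structure; separate
centering isolates exactly the phase-dependent part, which is what the
binned contrasts test.

Phases are binned into 24 overlapping 60° bins stepped by 15°; each phase
belongs to exactly four bins. Because tones are not uniformly distributed
over phase, each subject-bin's UNSTIM responses are summarised by a
Gaussian with their empirical mean and variance, from which 200 Monte Carlo
draws form a surrogate baseline. Per bin, the paired difference
(STIM−MC) − (UNSTIM−MC) is tested against zero across subjects with a
one-sample t-test and Benjamini–Hochberg FDR at α = 0.05 over the 24 bins
of one signal and metric (families are not pooled across signals or
metrics). The *preferred phase* readout is the bin centre maximising the
group-mean mean-centered STIM response — the quantity a phase-response
curve displays — while the FDR-corrected contrasts say where STIM and
UNSTIM differ reliably.

The Pairwise Response Index (PRI) works at the individual level: a bin's
STIM−MC contrast distribution is the 200 values (STIM mean − MC draw), each
ordered bin pair is compared with Welch's unequal-variance t-statistic, and
a bin's PRI is the average sign over its 23 comparisons, in [−1, +1]. We
read "the distribution obtained from the Monte Carlo procedure" as the
draw-level distribution; a trial-level alternative exists but has no
surrogate correction. Group PRI values are tested against zero per bin with
BH-FDR.

Spindle likelihood uses a resampling null: per bin, two-thirds of the
pooled UNSTIM trials are drawn without replacement 200 times; the null
reference is the geometric mean of the resampled likelihoods, with
zero-likelihood iterations contributing 1/(2m) (m = draws per iteration) so
the geometric mean stays defined. Subject likelihoods are expressed as
percentages of that null and compared STIM vs UNSTIM per bin with Welch
tests and BH-FDR. The null is pooled across subjects because per-subject
bins are often too sparse for a stable two-thirds resample.

The multidimensional analysis classifies each tone's three phases into
upstate/downstate and evaluates the eight conditions
{`---`, `U--`, `-U-`, `--D`, `UU-`, `U-D`, `-UD`, `UUD`} (slots: EEG-SO,
HR-LF, HR-HF; the targeted states are SO-upstate, LF-upstate,
HF-downstate). Per subject and condition: tone-locked ERPs over [−2, +10] s
on the broadband EEG with extrema sought in [0, +3] s, difference
waveforms, condition spectra, trial-mean SO amplitudes, and SWA expressed
as a percentage of the grand-mean unstimulated open-loop SWA (100 by
definition). Subject-level aggregation precedes group tests. Strategy
pairs are compared on per-subject differences with a Shapiro–Wilk gate
(α = 0.05): paired t when normality holds, Wilcoxon signed-rank otherwise.
The table reports both the ERP peak-to-peak and the per-trial mean SO
amplitude; enhancement-vs-open-loop deltas use the trial-mean, which is far
less sensitive to ERP latency jitter, with the ERP-based delta reported
alongside.

## The synthetic cohort

The generator produces, per subject: a block-structured hypnogram (wake/N1
onset, then N2→N3→N2→REM cycles; ≥ 60% N2/N3), arousal intervals
(5/h), occasional ±2000 μV artifact bursts (2/h), tones at uniform 15–30 s
intervals restricted to N2/N3, and two synchronized signals.

**EEG.** The SO band is modelled as a weak continuous 0.8 Hz rhythm (20 μV,
the phase carrier — far below detection thresholds on its own) into which
discrete waveforms are spliced with short crossfades: spontaneous SOs
(Poisson, 20/min of N2/N3, peak-to-peak ~N(160, 25) μV, duration 1.05–1.45 s,
phase-aligned to the rhythm) and tone-evoked SOs at a fixed 0.22 s latency.
The SO waveform is a single asymmetric cycle — a deep narrow trough (57% of
the amplitude over 43% of the duration) followed by a shallow wide peak,
the two halves having equal areas so high-pass filtering causes no baseline
shift — bracketed by small equal-area lobes that pin the delimiting
downward zero crossings to the waveform itself, mimicking the P200-like
positivity before an evoked K-complex. Injected waveforms are pre-scaled by
the inverse of the measured 0.5–4 Hz filter gain for this shape, so the
amplitude the *analysis* measures equals the configured value (zero-phase
filtering at these band edges attenuates 0.8 Hz content by roughly 13%,
which would otherwise shift every amplitude systematically). Spontaneous
durations are jittered around the rhythm period; wider jitter makes the
eventwise instantaneous frequency slip against the carrier and degrades the
measurable phase. The evoked amplitude follows

  amp = base + g_so·cos(φ_so − 75°) + g_lf·cos(φ_lf − 60°) + g_hf·cos(φ_hf + 120°),

clipped at zero, with defaults base = 170 μV (the scale of open-loop
stimulated SO amplitudes in adolescent sleep) and gains 20/10/10 μV. True
phases come from the noise-free oscillators, never from the noisy
composite. The evoked response also carries a trailing half-amplitude echo
cycle added on top of the background (the evoked delta burst), so
stimulated windows gain slow-wave power; the core cycle *replaces* the
local background via the crossfade, which keeps the measured amplitude
equal to the injected one in dense slow-wave sleep. Spindles are
Tukey-windowed 13 Hz bursts: uncoupled events at 1.5/min, plus SO-coupled
events — every spontaneous SO spawns one with probability 0.15; an evoked
SO with probability 0.15 + 0.3·cos(φ_so − 75°), clipped to [0, 1] — so
STIM and UNSTIM share the same coupling baseline and only the
phase-dependent part differs. A 1/f background (12 μV) completes the EEG.

**ECG.** A template beat (P-QRS-T deflections, 1 mV R peak) is placed at
times generated by RR = 60/HR with HR(t) = 60 + 3·sin(2π·0.1·t) +
2·sin(2π·0.25·t) + evoked transients; each RR is matched to the
mid-interval rate so the beat train is consistent with midpoint-anchored
analysis. Tones add a smooth 5-s HR transient of up to 5 bpm, largest when
the tone lands at SO phase 45° — the scale of tone-evoked cardiac
accelerations in sleeping humans — giving the cortical–cardiac analysis a
known structure to recover.

A zero-effect configuration (`null_effect_config()`) removes the evoked
base amplitude, all gains, the spindle coupling gain and the HR transient.
With a zero base, "STIM trials" are tones coincidentally followed by
spontaneous SOs — exactly the UNSTIM construction — so STIM and UNSTIM are
exchangeable and per-bin p-values are uniform. (A zero-gain but
nonzero-base configuration is *not* a null: evoked waveforms at a fixed
latency still interact with the ongoing rhythm phase.)

**What the generator does not emulate.** Realistic sleep architecture
(cycle-by-cycle SWA decline, stage-transition dynamics), SO frequency
drift and traveling waves, amplitude non-stationarity across the night,
respiratory sinus arrhythmia proper (HF is a fixed-frequency sinusoid),
ectopic beats, and EMG/EOG contamination. Passing tests therefore
demonstrate that the *pipeline* recovers known phase structure through
realistic detection noise, not that it is robust to every pathology of
clinical PSG.

## Problem sizes and tolerances

Validation cohorts are sized for a desk-scale run: preferred-phase
recovery uses 20 subjects × 2 h at 128 Hz (about 240 tones per subject);
null calibration uses 20 independent zero-effect cohorts of 6 subjects ×
1 h; the enhancement-ordering check uses 10 cohorts of 6 subjects × 1.5 h.
The default configuration is 256 Hz; analyses are sampling-rate agnostic
and 128 Hz halves the cost without touching any band of interest
(Nyquist 64 Hz vs a 30 Hz analysis ceiling). Monte Carlo draws (200),
resampling fraction (2/3) and α = 0.05 follow the analysis conventions
throughout. Subject-bin summaries require at least 5 STIM trials and 2
UNSTIM values (the Gaussian fit needs a variance); bins with fewer than 3
contributing subjects are reported untested and excluded from the FDR
family.

## Known limitations

Overlapping bins make neighbouring tests strongly correlated; BH-FDR
remains valid under this positive dependence but the effective number of
independent comparisons is nearer 6 than 24. The Hilbert phase of the
SO-band EEG is biased toward the evoked waveform's phase in the second
after a tone (the transform is non-causal), compressing measured STIM
phases toward the optimum; the generator's latency default makes this pull
land on the injected optimum, and the recovered preferred bins should be
read with that ±15–30° measurement blur in mind. UNSTIM windows are not
balanced across sleep cycles. The SWA of stimulated windows reflects both
the evoked response and whatever spontaneous activity the stimulation
displaced; absolute SWA percentages are therefore less interpretable than
their differences across phase-locking conditions.
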