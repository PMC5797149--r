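---
title: "Models and methods behind telemarr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind telemarr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telemarr)
```

## The problem

Long-term telemetric ECG in freely moving mice is the standard way to study
heart-rate regulation and the susceptibility to ventricular arrhythmias in
vivo. A typical protocol records a 96-h baseline (1 kHz single lead, 1 min
of waveform stored per 5-min block, plus a 5-min cage-activity parameter),
acute cross-over sessions in which isoproterenol or saline is injected and
the ECG is recorded continuously, and a second 96-h recording under chronic
metoprolol. The analysis asks: what are the day/night, minimal and maximal
heart rates; how does HR relate to activity; how strongly do the
beta-adrenergic drugs move it; and how many premature ventricular beats
(PVBs), couplets/triplets, ventricular tachycardia (VT) runs and ventricular
fibrillation (VF) episodes occur in the 5 h after the challenge.

Because raw animal recordings of this kind are rarely shareable, `telemarr`
pairs the analysis chain with a ground-truth-annotated generator that
emulates the recording protocol. Every analysis stage can therefore be
validated against a known truth, and calibration-recovery experiments can
check that published group-level numbers are reproduced when the generator
is set to them.

## The synthetic-data model

**Circadian heart rate.** The latent instantaneous HR is an additive
process: a circadian term, an activity-coupled term, a drug term, and a
mean-zero fluctuation, clipped to [150, 850] bpm. The circadian term moves
between a day (lights on, 07:00–19:00) and a night resting plateau with 1-h
raised-cosine ramps centred on the transitions; this reproduces the
step-like day/night traces of murine telemetry without discontinuities.
The fluctuation is an Ornstein–Uhlenbeck (AR(1)) process with a 30-s
correlation time and an SD of 70 bpm — mice swing over hundreds of bpm
between sleep and arousal within minutes, and this term carries that
dispersion. Each animal receives a random HR intercept (SD 20 bpm, shared
across its phases), matching the between-animal spread implied by published
group SEMs at n = 5–6.

**Activity.** Cage activity is logged as one value per 5-min epoch: exactly
zero with probability 0.5 (day) / 0.15 (night) — the animal at rest — and
otherwise gamma-distributed (shape 1.5) with strain-specific day/night
means, truncated at the transponder ceiling of 300 A.U. Activity couples
into HR through a saturating (Hill-type, K = 10 A.U.) gain, which
reproduces the monotone, flattening HR-versus-activity-class curves seen in
telemetry data.

**Calibration.** The day/night resting levels and the coupling gain are not
free: `calibrate_profile()` solves them so that (i) the expected minimum
valid-epoch HR over 96 h equals the profile's `hr_min` and (ii) the
expected day and night epoch means equal `hr_day_mean` / `hr_night_mean`.
The minimum is an extreme-value quantity: with 1-min epochs spaced 5 min
apart (far beyond the 30-s fluctuation correlation time) the rest-epoch
noise means are effectively independent Gaussians, so the expected minimum
follows from exact order statistics, evaluated by numerical integration
over the pooled day and night rest epochs at their calibrated level gap.
The mean targets use the analytic ramp weights and the analytic expectation
of the activity gain. A short fixed point resolves the circular dependence.
Recovery was verified by simulation: for the trough-317-bpm profile, 24
simulated animals return a mean 96-h minimum of 315.7 ± 4.1 bpm and day and
night means within 1 bpm of target.

**Drugs.** Chronic metoprolol subtracts a day/night-specific reduction
(defaults 50/70 bpm — blockade bites harder in the active phase) with the
same circadian ramps. Isoproterenol adds a double-exponential surge
$A\,(e^{-t/\tau_d}-e^{-t/\tau_r})$, peak-normalised to the profile's
`iso_peak_delta`, with $\tau_r$ = 3 min and $\tau_d$ = 50 min so that the
added term has declined below 1 bpm 300 min after injection — the
acute-protocol observation window. Each acute session injects twice, 30 min
apart, with the same agent; the protocol wording is ambiguous on whether
the two injections within a session can differ, and same-agent pairs are
the interpretation adopted here.

**Beats.** Sinus beat times come from exact inversion of the integrated
rate: beat *k* falls where $\int \mathrm{HR}/60\,dt$ crosses $u_0 + k$,
plus a 1.5% multiplicative RR jitter. Inversion is exact for time-varying
HR and produces the quasi-periodic RR structure of a heartbeat; a thinned
Poisson process was rejected because exponential inter-event intervals
would trip every RR-based criterion. For duty-cycled sessions beats are
generated only inside the recorded minutes.

**Arrhythmias.** Events are scheduled per class as homogeneous Poisson
counts with mean `rate × window / 5 h`, onsets uniform, re-drawn until all
onsets are at least 5 s apart so runs never fuse. Coupled beats are
couplets or triplets (30% triplets); VT run lengths follow 4 + Geom(0.5);
VF durations are lognormal(log 3 s, 0.4). Injection replaces k sinus slots:
the first PVB at 0.6 of the local RR, intra-run coupling 0.55 RR, and the
following sinus beat keeps its grid position, making the pause fully
compensatory (RR_pre + RR_post = 2 RR for an isolated PVB). PVBs carry
atypical morphology and no P wave; VF deletes all beats in its interval.

**Waveforms.** Beats are rendered as Gaussian-bump P-QRS-T templates at
mouse scale (QRS ≈ 12 ms); the PVB template widens the QRS 2.4×, raises R
1.4×, inverts the T and omits the P, so the morphology criterion is
objectively detectable. VF is a sum of three frequency-drifting (8–16 Hz),
amplitude-modulated sinusoids normalised to 0.4 mV RMS — irregular enough
that no 60-ms window repeats, which operationalises "no distinguishable
QRS". Optional baseline wander, white noise and artifact bursts complete
the model.

## Detection and classification

**QRS detection** is an energy pipeline tuned to mouse ECG: 10–50 Hz
band-pass, squaring, 12-ms integration, and a per-10-s threshold set to a
fraction of the *median provisional peak height* — a quantile-based
threshold is inflated by tall wide-QRS ectopy and drops normal beats,
whereas the median tracks amplitude drift and ignores the ectopic
minority. The 50-ms refractory period is enforced on refined R-peak times
with amplitude-priority suppression, because the energy envelopes of a
premature wide beat and its neighbour can merge even when the R peaks are
more than 50 ms apart.

**Template libraries** cluster −20/+40-ms beat windows greedily at a 0.95
normalized cross-correlation merge threshold; the asymmetric window
includes the T wave so that T-wave alteration lowers the match score.
Clusters need at least 3 members, and their mean waveform must have a crest
factor (peak/RMS) of at least 2.1: QRS-like shapes measure ≥ 2.4 while
fibrillatory arcs measure ≤ 1.8, and without this gate VF windows
self-cluster into "templates" that defeat VF detection. The most populous
cluster is hinted normal. Beats are matched at an unmatched threshold of
0.8; for the atypical-QRS criterion, failing to match the normal template
counts as atypical (matching an abnormal template or matching nothing),
which is how library-based semi-automatic workflows treat match failures.

**P-wave search** scans −50…−20 ms before the R peak, truncated to at
least 35 ms after the previous R so the previous T wave is excluded; the
−20-ms stop keeps wide premature QRS onsets out of the window. Windows
shorter than 12 ms are low-confidence and report no P.

**The PVB rule.** A beat is a PVB when it is premature — RR before it
below 0.8 of the rolling reference (median of the last 5 normal-flanked
intervals) — and at least 2 of 3 criteria hold: atypical QRS/T morphology,
atrioventricular dissociation (no P found), and a compensatory pause (RR
after it above 1.15 of the reference). The 0.8/1.15/k = 5 values separate
the generator's fully compensatory ectopy from sinus arrhythmia in fixture
sweeps and are exposed in the configuration. The reference is iterated to
a fixed point, excluding intervals adjacent to PVB-labeled beats: long VT
runs otherwise contaminate a single-pass rolling median with their own
cycle length and their tails are missed. Runs of consecutive PVBs map to
the grammar 1 → PVB, 2 → couplet, 3 → triplet, ≥ 4 → VT, each run counted
once; couplets and triplets pool as "coupled beats" at summary level, and
the per-class columns count runs, not member beats. VF is detected from
1-s windows containing no template-matched beat while the RMS stays above
3× the noise floor; VF intervals override beat-level labels.

## Heart-rate analytics

Epoch HR is 60000 over the mean within-minute RR — equivalently the mean
beat rate over the recorded minute — and an epoch is valid with ≥ 20 beats
and ≤ 20% artifact overlap. Naturally occurring minimum/maximum HR are
taken over 1-min epoch means (the telemetry duty cycle makes the epoch the
observable unit), day/night assignment uses the epoch start time, and the
activity classes are half-open intervals (0,5], …, (30,300] with class 0
reserved for exactly zero activity — the only partition consistent with a
dedicated zero class given the printed bin labels. Acute sessions use 10-s
epochs, which resolve the isoproterenol peak that 1-min epochs blur. ΔHR
is the baseline-minus-metoprolol difference of day (night) means per
animal.

## Group statistics

The battery mirrors the conventions of such studies: Shapiro–Wilk
normality screening; one-way ANOVA followed by Student–Newman–Keuls, with
studentized-range tail probabilities from numerical integration
(`ptukey`), span-dependent critical values, the blocking rule, and
reported p-values equal to the maximum over containing spans (with two
groups this reduces exactly to the pooled t-test); two-way ANOVA with
Sidak-adjusted within-stratum comparisons on the pooled error, the family
being the comparisons actually reported; and Kruskal–Wallis with
tie-corrected Dunn z statistics, Sidak-adjusted for consistency with the
parametric branch (the correction variant is configurable since the
convention varies). Descriptives are median with 5–95 percentiles,
quartiles and mean ± SEM, using type-7 quantiles.

## Validation sizes and what passing shows

The test suite validates: exact grammar and criteria behaviour; zero
beat-level confusion of truth-bypass classification on full acute
sessions; equality of the waveform path and the truth-bypass path on
noiseless fixtures; QRS sensitivity/PPV of 1.0 noiseless and ≥ 0.98 at
10 dB SNR; Poisson calibration of the scheduler (400 windows); recovery of
the burden fold-difference between the susceptible and protected strain
profiles (200 cohorts of 6 + 6 animals), of the per-animal PVB count at
the programmed rate (500 animals), and of the programmed metoprolol
reduction and circadian trough (20 animals each over 96 h); and simulated
type-I error within [0.03, 0.07] for all three test families at n = 6 over
5000 replicates. These sizes keep the full suite within minutes on one
core while leaving Monte-Carlo standard errors well below the tested
tolerances.

The generator emulates circadian HR, activity coupling, drug
pharmacodynamics, beat-level arrhythmia structure and waveform morphology,
but real recordings contain features it does not: electrode drift and
dropout, morphology change within an animal over days, supraventricular
ectopy, heat/stress artifacts correlated with handling, and HR-dependent
repolarization changes. Passing the suite therefore demonstrates that the
analysis chain is correct for signals obeying the stated model, not that
the detector's operating point is optimal for any particular hardware.

## Known limitations

- The waveform path is validated on minutes-long fixtures; applying it to
  a full 96-h study at 1 kHz is computationally possible per session but
  not materialised by `simulate_study()`, which returns beat-level truth.
- VF detection presumes fibrillatory energy within the detector band; fine
  VF below the RMS gate would be missed, as it would be by an amplitude
  criterion on real hardware.
- The statistics module covers the independent-groups designs used here;
  repeated-measures and mixed models are out of scope.
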