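# telemarr

Telemetric ECG simulation and ventricular-arrhythmia analysis in mice.

Cardiovascular research groups use implanted telemetry transponders to
record single-lead ECG and cage activity from freely moving mice over days,
and then quantify heart-rate regulation (day/night means, naturally
occurring minima and maxima, activity-normalized HR), responses to
beta-adrenergic blockade (metoprolol) and stimulation (isoproterenol), and
the resulting ventricular arrhythmias. `telemarr` implements that full
analysis chain together with a ground-truth-annotated synthetic-data
generator, so every stage is testable without animal data:

- **Synthetic telemetry studies** — circadian HR model (raised-cosine
  day/night transitions, Ornstein–Uhlenbeck fluctuation, per-animal
  intercepts), zero-inflated gamma cage activity with saturating HR
  coupling, drug pharmacodynamics, Poisson arrhythmia scheduling with a
  run-length grammar, and 1-kHz P-QRS-T waveform synthesis including VF and
  artifacts. Circadian levels are calibrated by exact order statistics so
  that the observable 96-h minimum epoch HR matches the profile's target.
- **Beat detection** — a murine-tuned energy-pipeline QRS detector,
  animal-specific waveform template libraries (greedy NCC clustering),
  morphology matching, P-wave search, artifact flagging.
- **Rhythm classification** — the 2-of-3 premature-ventricular-beat
  criteria (atypical QRS/T, AV dissociation, compensatory pause) on a
  rolling RR reference, the run grammar (1 → PVB, 2 → couplet,
  3 → triplet, ≥ 4 → VT), VF detection by absence of distinguishable QRS
  complexes, and windowed event counting.
- **HR analytics** — per-minute epochs over the 1-min-per-5-min duty
  cycle, day/night summaries, min/max HR, activity-class binning (0,
  (0,5], …, (30,300] A.U.), metoprolol ΔHR, and the acute isoproterenol
  response on 10-s epochs.
- **Group statistics** — normality screening, one-way ANOVA with
  Student–Newman–Keuls, two-way ANOVA with Sidak, Kruskal–Wallis with
  Dunn, and the descriptive formats (median, 5–95 percentiles, mean ± SEM).

The central beat-level rule: a beat is a PVB when its preceding RR is below
0.8 of the rolling reference (median of the last 5 normal intervals) *and*
at least 2 of 3 criteria hold — atypical QRS configuration with T-wave
alteration, atrioventricular dissociation, compensatory post-extrasystolic
pause (RR after the beat above 1.15 of the reference). Runs of consecutive
PVBs form couplets, triplets and VT (≥ 4 beats); each run counts once.

## Worked example

```r
library(telemarr)

strains <- default_strains()[c("Balb/c", "BS")]
design  <- study_design(strains, n_per_strain = c(3, 3),
                        longterm_hours = 24, seed = 42)
study   <- simulate_study(design)
report  <- pipeline_run(study)
print(report)
```

```
<study_report> 6 animals

Heart rate (long-term recordings):
  group baseline_min baseline_max metoprolol_min metoprolol_max  delta_day
 Balb/c 342 ± 13 bpm 739 ± 13 bpm   327 ± 10 bpm   674 ± 11 bpm 54 ± 2 bpm
     BS 423 ± 10 bpm 753 ± 10 bpm   392 ± 10 bpm   682 ± 11 bpm 54 ± 3 bpm

Ventricular arrhythmias, 5 h after isoproterenol:
  group               PVB    Coupled beats               VT              VF
 Balb/c 164.7 ± 9.7 (3/3) 44.3 ± 2.2 (3/3) 13.7 ± 1.5 (3/3) 4.0 ± 1.0 (3/3)
     BS  42.3 ± 2.4 (3/3) 14.7 ± 1.3 (3/3)  1.3 ± 0.9 (2/3) 0.0 ± 0.0 (0/3)
      Total events
 226.7 ± 8.4 (3/3)
  58.3 ± 1.9 (3/3)

Total events: Kruskal-Wallis H = 3.86, p = 0.0495
```

Reading the output: each HR cell is the group mean ± SEM over animals of a
per-animal 96-h-style summary (here 24 h for speed) — e.g. the Balb/c
profile's naturally occurring minimum sits far below BS's, while `delta_day`
shows the programmed ~50-bpm day-time metoprolol reduction recovered in both
strains. Each arrhythmia cell is "mean ± SEM (animals affected / group
size)" of event counts over the 5 h after the isoproterenol injection; the
susceptible profile (Balb/c) carries a roughly four-fold higher total burden
than the protected one (BS) and is the only group with VF, and the
Kruskal–Wallis test flags the group difference at p < 0.05.

Waveform-level analysis works on any `ecg_record` (simulated via
`synthesize_ecg()` or read from CSV with `read_record()`):

```r
res <- analyze_record(record)   # QRS detection -> templates -> criteria
res$events                      # classified PVB/couplet/triplet/VT/VF events
```

A thin command-line wrapper lives at `inst/cli/telemarr.R`
(`telemarr.R simulate|run --config cfg.yaml --out dir`).

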