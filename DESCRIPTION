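Package: telemarr
Title: Telemetric ECG Simulation and Ventricular Arrhythmia Analysis in Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of long-term telemetric ECG studies in
    freely moving mice. Provides a ground-truth-annotated synthetic data
    generator (circadian heart-rate model, activity coupling, beta-adrenergic
    drug responses, injected ventricular arrhythmias, 1 kHz ECG waveforms),
    murine-tuned QRS detection with animal-specific waveform template
    libraries, Lambeth-Conventions-style classification of premature
    ventricular beats, couplets, triplets, ventricular tachycardia and
    fibrillation, circadian and activity-normalized heart-rate analytics, and
    the group-comparison statistics commonly applied to such studies (one-way
    ANOVA with Student-Newman-Keuls, two-way ANOVA with Sidak, Kruskal-Wallis
    with Dunn post-hoc tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
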