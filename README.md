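# mfpd — multi-feature probabilistic QRS detection

`mfpd` is an R package for online, real-time detection of QRS complexes
in single-lead ECG, built for the regime where single-feature detectors
fail: long-term recordings corrupted by baseline wander, muscle
artifact and electrode-motion transients.

Each candidate event (a local maximum of a squared-slope transform of
the band-passed ECG) is described by three features — squared slope
`s`, band-passed amplitude `a`, and absolute correlation `c` with an
adaptive beat template. For each feature the detector learns, online, a
pair of class-conditional densities (Gamma for `s`, generalized normal
for `a`, Beta for `c`) under the hypotheses H1 "true beat" and H0 "not
a beat", and forms the per-feature posterior `P_i(H1 | x_i)` by Bayes'
rule. The decision fuses the posteriors with weights proportional to
each feature's Kullback–Leibler divergence `D(f_i1 || f_i0)` — capped
so the largest normalized weight never exceeds 2/3 — and validates the
candidate when

```
sum_i  w_i · P_i(H1 | x_i)  >  λ ,      w_i = D̄_i / Σ_j D̄_j ,
D̄_i* = min( D_i*, 2 Σ_{h≠i*} D_h )     (i* = argmax_i D_i)
```

so features that currently separate the two classes well dominate, and
features corrupted by the present noise are automatically discounted.
The package includes the semi-analytic KL divergence between two
generalized normal distributions with *unequal* positions (binomial
expansion into complete/incomplete gamma functions for integer target
shapes, monotone ratio interpolation between them otherwise).

Also included: a minimal WFDB codec (signal formats 212/16 and beat
annotations), an SNR-controlled noise-mixing benchmark builder, a
synthetic annotated ECG generator with the three benchmark noise
classes, a Pan–Tompkins bootstrap detector used for initialization, and
ANSI/AAMI-style beat-by-beat scoring (Se, +P, DER, jitter, delay) with
a 50-ms match window.

## Worked example

```r
library(mfpd)

sim <- simulate_ecg(duration_s = 120, mean_hr = 70, hr_sd = 3,
                    fs = 360, seed = 7)
det <- detect(sim$record)
det
#> <detection_set> 140 beats, latency 140 ms, 0 reset(s)

score_record(match_beats(sim$annotations, det))
#> <score_report> TP=140 FP=0 FN=0 | Se=100.00% +P=100.00% DER=0.00%
#>   jitter -11.13 +/- 0.83 ms
```

The two-minute synthetic record has 140 annotated beats; the detector
initializes its densities on the first 40 via the Pan–Tompkins
bootstrap, then validates candidates by divergence-weighted fusion —
here every beat is found and everything validated is a true beat.
The −11 ms mean jitter is the
residual offset between the slope-transform peak and the annotated R
apex; the 140-ms latency is the fixed pipeline delay (filter group
delays plus the trailing half of the correlation window).

Degradation under noise, per kind and SNR:

```r
noise <- simulate_noise_record("muscle", 120, 360, seed = 5)
noisy <- mix_noise(sim$record, noise, snr_db = 0, kind = "muscle")
score_record(match_beats(sim$annotations, detect(noisy)))
```

A command-line wrapper over the same functions lives in
`inst/cli/mfpd.R` (`simulate`, `mix`, `detect`, `eval` subcommands).

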