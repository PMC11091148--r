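---
title: "Cancellable ECG templates by output decorrelation: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cancellable ECG templates by output decorrelation: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cancellableECG)
```

This vignette is the package's own account of what it computes and why the
design is the way it is. It states no empirical result that the test suite
and `scripts/acceptance.R` do not themselves compute.

## The model

A subject's ECG `s1` and an auxiliary audio signal `s2` (equal length `N`,
assumed zero-mean and mutually independent) are treated as the sources of a
2×2 linear time-invariant convolutive system with unit direct paths:

$$x_1(k) = s_1(k) + \sum_{i=0}^{p} h_{12}(i)\, s_2(k-i), \qquad
  x_2(k) = \sum_{i=0}^{p} h_{21}(i)\, s_1(k-i) + s_2(k).$$

Separation applies FIR cross-filters of order $q$,

$$y_1(k) = x_1(k) + \mathbf{w}_1^\top \mathbf{x}_2(k), \qquad
  y_2(k) = x_2(k) + \mathbf{w}_2^\top \mathbf{x}_1(k),$$

with $\mathbf{x}_i(k) = [x_i(k), \ldots, x_i(k-q)]^\top$. Independent
sources have zero cross-correlation at every lag, so the weights are chosen
to minimise the decorrelation cost

$$C(\mathbf{w}_1, \mathbf{w}_2) = \sum_{l=l_1}^{l_2} r_{y_1y_2}(l)^2,
  \qquad r_{ab}(l) = \tfrac{1}{N}\textstyle\sum_k a(k)\, b(k+l).$$

Substituting the output definitions into $r_{y_1y_2}$ gives the closed form
the whole solver rests on:

$$r_{y_1y_2}(l) = r_{x_1x_2}(l)
  + \sum_i w_1(i)\, r_{x_2x_2}(l+i)
  + \sum_j w_2(j)\, r_{x_1x_1}(l-j)
  + \sum_{i,j} w_1(i)\, w_2(j)\, r_{x_2x_1}(l+i-j).$$

Two points deserve attention. First, the lag index runs *forward*
(`l + i`) in the $\mathbf{w}_1$ autocorrelation term but *backward*
(`l - j`) in the $\mathbf{w}_2$ term; a symmetric-looking variant with both
running forward does not expand correctly from the definitions. The
implementation follows the re-derivation, and the property test comparing
the closed form against brute-force filtering of the actual signals (the
oracle test in `test-bss.R` and the acceptance suite) would catch either
index convention being wrong, since the two conventions disagree whenever
the input autocorrelation is asymmetric around the window. Second, the
bilinear term couples the two weight vectors through the `(2q+1)`-row
stacked cross-correlation matrix; arranging the partner weight into a
banded `(2q+1) x (q+1)` matrix makes the term linear in each weight vector
separately.

Because $C$ is an exact quadratic in $\mathbf{w}_1$ for fixed
$\mathbf{w}_2$ (and vice versa), each half-step solves its least-squares
problem in closed form, and the alternation is coordinate descent on the
one shared objective: the cost never increases, which the suite asserts on
every run. Iteration stops when the relative change of $C$ falls below
`conv_tol`. The stopping rule is deliberately phrased on the cost: phrasing
it on a derivative would require choosing a norm and a differencing scheme
that nothing downstream depends on, while the cost is the quantity the
algorithm is actually driving.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `q` | 4 | taps − 1 | covers cross-path orders up to 4; more taps buy nothing on the synthetic fixtures and slow the normal equations |
| `l1`, `l2` | −25, 25 | samples | 51 lags ≈ 0.1 s at 500 Hz: wide enough to constrain 2(q+1) = 10 parameters ~5× over, short relative to N so lag-window edge effects stay O((q+|l|)/N) |
| `conv_tol` | 1e-4 | relative | the 0.01% relative-change rule |
| `max_iter` | 100 | iterations | ample for the template pipeline (typically < 10); ill-conditioned recovery problems are run with a larger budget, see Limitations |
| `ridge` | 1e-8 | relative to mean diag | Tikhonov guard for near-singular normal equations (e.g. an all-zero channel); small enough never to perturb a well-posed solve |
| binarization | median | — | balanced bits and affine invariance; mean thresholding would inherit baseline drift |
| `threshold` | 0.5 | score | midpoint of the wide gap between imposter scores (≈ 0) and genuine scores on matched keys |

## What the synthetic data emulates — and what it does not

`generate_synthetic_ecg()` builds each beat from five Gaussian bumps
(P, Q, R, S, T) with textbook lead-II amplitude/width/offset proportions on
a strictly regular beat grid, plus white Gaussian baseline noise
(sd 0.05 relative to R). Default acquisition is 20 s at 500 Hz, a common
single-lead protocol. `generate_synthetic_audio()` is three random
sinusoids in the low audio band plus 20% low-pass-filtered noise power,
exactly mean-centred. `simulate_subjects()` gives each identity its own
heart rate (55–95 bpm) and per-wave morphology jitter, with acquisitions
differing by their baseline-noise realisation.

This emulates exactly what the pipeline needs — quasi-periodicity,
subject-distinctive morphology, an uncorrelated narrowband auxiliary
channel, seedable repeatability — and nothing more. It does **not** model
heart-rate variability, respiration, electrode motion artifacts,
arrhythmia, or acoustic realism of the audio. Consequently, passing tests
show the *mechanism* is correct (separation, whitening, scoring, sweep
logic); they do not predict error rates on ambulatory recordings, where
intra-subject variability is far richer. WFDB readers are provided so real
records can be substituted directly.

## Evaluation protocol

Per subject, acquisition 1 enrolls and the remaining acquisitions probe;
every probe is scored against every enrollment, same-subject pairs genuine,
the rest imposter. Imposter probes are regenerated with the *claimed*
subject's key, so an imposter is wrong in both body and key — the realistic
attack when keys are device-bound.

Two probe regimes exist because they answer different questions.
`probe_source = "fresh"` (default) probes with an independent
re-acquisition and measures enrollment repeatability. `probe_source =
"replay"` probes with the enrollment record itself, optionally through
additive white Gaussian noise at `snr_db`; it measures channel-noise
robustness. The distinction matters quantitatively: with fresh
acquisitions the genuine score is bounded by the fraction of samples whose
clean amplitude stands clear of the median, because baseline-segment bits
are re-randomised by each acquisition's own noise on both sides of the
comparison (the measured genuine mean is ≈ 0.49 while imposters sit at 0 —
still a complete separation, EER = 0). Under replay at 10 dB the enrollment
and probe share the baseline realisation, bits stay correlated, and the
genuine mean rises to ≈ 0.66. Reporting a noise-robustness number from the
fresh regime would conflate two noise sources; the acceptance script
reports both regimes explicitly.

## Numerical choices

- **Biased (1/N) correlation estimator** throughout: it keeps implied
  autocorrelation matrices positive semi-definite, so the normal equations
  are well-posed; the small-lag bias is identical on both sides of the
  oracle comparison.
- **Mean-centring** of both observations before any correlation estimate,
  matching the zero-mean model assumption; the synthetic audio is also
  centred exactly at generation.
- **Causal FIR filtering with zero initial conditions** (full convolution
  truncated to N). The closed-form and brute-force cross-correlations then
  differ only by edge terms of order `(q + |l|_max)/N`, the tolerance the
  oracle tests use.
- **Gaussian bump support truncated at 8σ**, keeping truncation error below
  1e-12 of the wave amplitude so the noiseless ECG is periodic to
  float precision.
- **Degenerate inputs**: an all-zero channel yields zero weights and a
  pass-through output rather than an error; a constant signal is rejected
  at binarization because a zero-variance template cannot be scored;
  separation non-convergence is reported in the result flag and template
  provenance, never thrown.
- **EER interpolation**: empirical FAR/FRR are step functions that may
  never be exactly equal; the crossing is located between adjacent sweep
  thresholds and both rates are linearly interpolated there (their average
  is reported if they differ in the last digit).
- **Tie-break**: a score exactly at the threshold rejects (strict
  inequality), the conservative choice for an authentication gate.
- **Template store**: JSON lines with hex-packed bits, little-endian bit
  order within each byte, exact bit length recorded — byte-identical round
  trips are asserted in the suite.
- **Keys** are seeded PRNG bits so enrollment is reproducible; production
  deployments should draw keys from OS entropy and store them separately
  from templates.

## Problem sizes

The suite and the acceptance script run at the sizes the properties are
stated for: n = 10^4 samples (20 s at 500 Hz) for signal-level properties,
10 subjects × 2 acquisitions for population metrics, 100 random instances
for the closed-form-vs-brute-force and threshold-sweep oracles, n = 10^5
for SNR calibration checks. All complete in well under a minute on one core.

## Known limitations

- **Near-degenerate recovery geometry.** With equal-variance white sources
  the observation autocorrelations nearly coincide, leaving the cost
  surface with a soft valley along joint perturbations of `w1(0)` and
  `w2(0)`; the finite-sample minimiser can drift several hundredths from
  the population optimum `(-h12, -h21)` at n = 10^4, and convergence along
  the valley is slow (hundreds of alternations). This is a property of the
  objective, not the solver — a joint quasi-Newton minimisation of the same
  empirical cost lands in the same place. Unequal source powers or longer
  records sharpen the valley.
- **Binarization is baseline-dominated for ECG.** Roughly half of a resting
  ECG sits near its median, so those bits are noise-driven; genuine scores
  under fresh acquisitions plateau near the fraction of "decided" samples.
  The margin over imposters remains large, but absolute genuine scores are
  not comparable across binarization rules.
- **Security is statistical, not cryptographic.** XOR with a leaked key is
  trivially invertible to the binarized separation output; the
  non-invertibility argument assumes the key is secret and is supported
  here by whitening statistics (correlation and Hamming distance against
  the raw ECG's sign bits), not by a formal proof.
- The evaluation protocol is this package's own; no claim is made that it
  reproduces any particular published benchmark protocol.
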