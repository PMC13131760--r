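---
title: "Predicting hearing thresholds from consonant confusions: models and methods"
author: "qvcv package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting hearing thresholds from consonant confusions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qvcv)
```

## The measurement problem

A closed-set consonant identification test presents vowel-consonant-vowel
tokens (such as /aka/) in speech-shaped noise and asks the listener to pick
the consonant from a fixed response panel. Consonant identity rides on
fine-grained acoustic cues — rapid onsets, spectral detail, temporal fine
structure — that degrade early with cochlear damage, so the pattern of
confusions is informative about hearing status well beyond a single
percent-correct score. This package implements the computational core of
such a test: panel design, threshold prediction, residual-loss detection,
repeatability analysis, and hearing-aid-benefit quantification, plus a
synthetic-listener simulator that makes every analysis testable end to end
without human data.

## Panel design: SNR90 normalization and AUC screening

Each token's performance-versus-SNR curve is modelled as a logistic
psychometric function with a fixed guess floor and lapse ceiling,

$$P(s) = \gamma + (1-\gamma-\lambda_\ell)\,\sigma\!\big(\beta\,(s - m)\big),$$

with guess rate $\gamma = 1/14$ (fourteen response buttons), lapse
$\lambda_\ell = 0.02$, midpoint $m$ (dB SNR) and rate $\beta$ (1/dB).
`fit_psychometric()` maximizes the binomial likelihood with a weak Gaussian
prior on $\log\beta$ (mean $\log 0.5$, sd 1.5) so that two- and three-point
designs remain stable; the fit is deterministic (multi-start Nelder-Mead).
`snr90()` solves $P(s) = 0.90$ — the SNR at which normal-hearing listeners
get 90% correct. Normalizing every token to its SNR90 places
hearing-impaired listeners on the steep part of the function, which is what
makes the confusions discriminative. Crossings are only extrapolated 6 dB
beyond the measured SNR range; outside that, tokens are flagged `saturated`
or `unreached` and handled qualitatively, and `propose_snr_grid()` returns
the refined \{SNR90 − 3, SNR90, SNR90 + 3\} grid rounded to integer dB.

Token screening uses the Mann-Whitney area under the ROC curve
(`auc_mann_whitney()`): the probability that a randomly chosen hearing-loss
listener scores below a randomly chosen normal-hearing listener, ties
counted one half. Consonants with AUC below 0.9 are dropped, the vowel
context with the best (highest-median, then lowest-IQR) AUC distribution is
kept, and each retained token gets its most discriminative SNR (ties going
to the lower, harder SNR). The packaged result of this process is
`qvcv_default_panel()`: ten consonants (b d g k n s sh t v z) in /a/
context at fixed per-token SNRs. The per-listener unit of analysis for all
AUCs is the proportion correct on that token's trials — the only quantity
available at that granularity.

## Threshold prediction: vectorize, reduce, regress

`fit_pta_model()` is the package's central model. Per listener, the
confusion matrix over the ten panel consonants (plus an "other" column that
also absorbs off-panel button presses) is row-normalized and flattened into
a 110-dimensional proportion vector. Features are centered, reduced by PCA
to the smallest number of components explaining 95% of training variance,
and the measured pure-tone average (PTA, mean threshold at 1, 2, 4 kHz) is
regressed on the unit-variance component scores with a ridge penalty,

$$\tfrac12\lVert y - \alpha - Z\beta\rVert^2 + \lambda\lVert\beta\rVert^2,
\qquad \lambda = 3,$$

with the intercept unpenalized. The penalty convention matters — $\lambda$
has no meaning without it — so it is fixed and documented here: $Z$ holds
unit-variance PCA scores and the residual term carries the factor 1/2.
Generalization uses repeated random 70/30 train/validation splits (default
100): centering, PCA and the regression are all refitted on each training
split, and a listener's cross-validated predicted PTA (PPTA) is the average
of predictions from the splits that held that listener out. A
ridge-penalized logistic head on the same scores provides binary
normal-vs-impaired classification.

Two normalization modes exist. The default centers the proportions only;
`"standardize"` additionally scales each cell to unit variance. Centering is
the default because the features already share a probability scale:
standardizing inflates rarely-confused, near-constant cells to unit
variance, hands most of the retained PCA variance to binomial sampling
noise (roughly 36 retained components instead of 14 on a 60-listener
cohort), and measurably worsens held-out prediction.

A continuous threshold in dB requires a linear response model, so the PPTA
head is ridge *linear* regression; regularized *logistic* regression is
used where the target is genuinely binary (normal-vs-impaired and
excess-loss detection). Predictions are clipped to [−10, 80] dB HL.

## Audibility baseline, residual loss, excess loss

Because the test is normalized to ~90% correct for normal hearing, it
cannot resolve differences among listeners whose thresholds are better than
roughly 15 dB HL; predicted PTA flattens there. `fit_audibility()` fits the
piecewise baseline $a(p) = \max(f, p)$ with the floor $f$ as the single free
parameter, by exact minimization of the piecewise-quadratic least-squares
objective (the optimum on each inter-knot interval is the mean of the
included predictions, clamped; all intervals are enumerated). The fit is
flagged when no listener lies below the floor.

Residual hearing loss is the part of the perceptual deficit the audiogram
does not explain: $\mathrm{RHL} = \mathrm{PPTA} - a(\mathrm{PTA})$.
Listeners with RHL strictly above 5 dB — the test's repeatability limit —
are flagged as having *excess loss*. `excess_loss_auc()` asks the harder
question: can excess-loss status be predicted from the confusion features
alone, without the audiogram? It cross-validates a PCA + ridge-logistic
classifier over repeated splits and reports the ROC AUC of the averaged
held-out scores.

## Repeatability and hearing-aid benefit

`session_pair_stats()` gives the Pearson correlation and mean absolute
difference (MAD) between two sessions. `mad_vs_trials()` estimates how
repeatability improves with test length: for each candidate trial count it
draws token-balanced subsamples (without replacement, stratified over the
consonant-by-recording tokens so per-token counts differ by at most one)
from each session, scores them (percent correct, and PPTA when a model is
supplied), and averages the across-listener MAD over resamples with a
2.5/97.5 percentile interval. Subsampling rather than first-$n$ truncation
removes order effects and is fully seeded; truncation remains available as
an option. `quicksin_reference()` packages the clinical comparison
constants (repeatability limits 2.5 and 5 dB; 25 trials per minute; one
minute per QuickSIN list).

`hearing_aid_benefit()` scores benefit on two scales: percentage points of
recognition and decibels of predicted loss (unaided PPTA minus aided PPTA;
positive means the aid reduced the predicted loss). The dB benefit is
*significant* when it strictly exceeds the 5 dB repeatability limit.
Percent-correct deltas carry no significance flag because only the dB
limits are established. `benefit_report()` adds the normal-hearing ceiling
check (aided score > 90%).

## The synthetic-listener generator

The generator exists so that every analysis above can be exercised, with
known ground truth, on cohorts with the statistical structure the analyses
assume. Its defaults are the study conditions used throughout the tests:
60 listeners, 15 per hearing category (normal −10–15, slight 16–25, mild
26–40, moderate 41–55 dB HL, drawn uniformly within bands), two 100-trial
sessions on the default panel (10 consonants x 2 recordings x 5
repetitions).

A listener's *effective loss* is the true PTA plus any excess-loss offset,
minus any aided relief, floored at −10 dB HL. Each token's probability of a
correct response is

$$P = \gamma + (1-\gamma-\lambda_\ell)\,
 \sigma\!\big(b\,(s - m - c\,\max(0, L - 15))\big),$$

where $L$ is effective loss and $c$ is the token's loss shift: hearing loss
above a 15 dB HL knee moves the psychometric function to higher SNRs. This
is the simplest mechanism that reproduces both the monotone decline of
score with PTA and the audibility-function knee. `calibrate_token_models()`
sets each midpoint $m$ so that a listener at the knee scores exactly the
target (0.90) at the token's panel SNR — the SNR90 normalization by
construction. Slopes are drawn uniformly from 0.25–0.45 /dB (peak slopes of
roughly 6–10 percentage points per dB, typical of consonant identification)
and loss shifts from 0.2–0.35 dB/dB, which places moderate losses near
25–60% correct. Fixed presentation level is not modelled acoustically; it
is absorbed into the loss-shift mechanism.

Error responses are drawn from a confusion kernel: a softmax (temperature
0.7) over negated articulatory distance (weighted Hamming distance on
voicing/place/manner, weights 1/1/2, with the "other" button at
pseudo-distance 2), so /s/ is confused with /sh/ far more than with /m/.
Excess-loss listeners differ in two ways: their offset (default 10 dB) adds
effective loss the "audiogram" does not show, *and* their errors are drawn
from a voicing-blind kernel (voicing weight 0). The second part models what
excess loss is understood to be — suprathreshold temporal-processing
deficit rather than attenuation — and is what makes excess status
detectable from confusion patterns alone; a severity offset by itself is
information-theoretically ambiguous without the audiogram (an excess
listener at PTA $p$ would be indistinguishable from an ordinary listener at
$p+\delta$, capping the detection AUC near 0.6 regardless of the
classifier).

All randomness flows through one seeded generator; cohorts are
bit-reproducible given a seed.

### What the simulator does and does not emulate

It emulates: the monotone decline of score with PTA, ~90% normal-hearing
performance at panel SNRs, articulatorily structured confusions, a
subgroup whose perception is worse than its audiogram predicts, aided
relief, and balanced session designs. It does *not* emulate: session-level
listener state (attention, criterion drift — between-session differences
are purely binomial, so repeatability curves lack the noise floor real
test-retest data show, and keep improving with trial count longer than
real curves plateau); per-recording differences (the two recordings share
one token model, consistent with pooling them in scoring); vowel-context
acoustics (a 13-consonant panel in any vowel context is available for
selection studies, with noisiness set by slopes and trial counts); and
acoustic waveforms generally. Passing tests therefore demonstrate the
pipeline's statistical behaviour under these assumptions, not performance
on human data.

### Known limitations observed on the calibrated cohorts

Two behaviours of the full pipeline on these cohorts are worth knowing.
First, ridge shrinkage plus the linear form compress predictions toward the
cohort mean, so residual losses of ordinary hearing-loss listeners average
a few dB below zero rather than exactly zero; the excess-versus-ordinary
*separation* is preserved. Second, when excess-loss listeners are part of
the training cohort with audiogram labels, the regression can exploit their
distinctive confusion signature to pull their predicted PTA back toward the
audiogram, which attenuates the very residual loss the signature signals.
The per-listener accuracy of the residual-loss estimate is bounded by the
pipeline's linearity: a maximum-likelihood inversion with known token
models recovers effective loss to about 1.6 dB on the same data, while the
linear pipeline achieves 3.5–4.5 dB per hearing-loss listener. These are
properties of the fixed pipeline (linear PCA + ridge at $\lambda = 3$), not
of the estimator implementations.

## Numerical choices and degenerate inputs

* Psychometric fits: degenerate data (all correct or all wrong everywhere)
  pin the midpoint at the extrapolation bound and are flagged; targets
  outside $(\gamma, 1-\lambda_\ell)$ are errors.
* Category banding rounds half-up to integer dB before comparison; PTAs
  above 55 dB HL are outside the inclusion range and rejected.
* The audibility fit enumerates inter-knot intervals, so it finds the global
  least-squares floor exactly; zero-noise inputs recover the floor to
  machine precision.
* Excess-loss flagging uses strict `>` at the threshold.
* Ties in SNR selection go to the lower SNR; ties in vowel selection to the
  smaller IQR, then alphabetical order.
* Repeated-split cross-validation (not a single split) is used so every
  listener receives a held-out prediction; with 100 repeats of a 70/30
  split the chance of a listener never being held out is negligible, and a
  warning is raised otherwise.
* Serialized models store full-precision doubles (JSON, `digits = NA`) and
  restore to numerically identical predictions; tabular reports are written
  at six decimals so repeated runs are byte-identical.

## Problem sizes used in the packaged analyses

The packaged tests and the acceptance script run the pipeline at the study
scale it is designed for — 60-listener cohorts, 200 trials per listener,
100 cross-validation repeats — averaged over ten replicate cohorts;
property-style checks use reduced cohorts (8–24 listeners) where the
property is scale-free. These sizes are the package's chosen reference
conditions and complete in well under a minute each on a single CPU.
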