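---
title: "Modelling sigma70 promoter strength from hexamer sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sigma70 promoter strength from hexamer sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promstrength)
```

## The problem and the model

Constitutive *E. coli* promoters recognized by the σ⁷⁰ holoenzyme carry two
conserved hexamers, centred roughly 35 and 10 bp upstream of the
transcription start site, with canonical consensi TTGACA and TATAAT. How
well a promoter's hexamers match these profiles largely determines how
often transcription initiates. `promstrength` turns that observation into a
quantitative predictor in two stages.

**Stage 1 — generative sequence model.** Each element gets a position
weight matrix built from a curated hexamer collection. Counts at position
$i$ are smoothed with a pseudocount of total mass $s$ apportioned according
to a background $q$ derived from the genomic GC content (50.8%), and
converted to log-odds:

$$w_{ib} = \log_2\!\frac{(c_{ib} + s\,q_b)/(n + s)}{q_b}.$$

A hexamer's score is the sum of its positional weights; it is positive when
the sequence looks more like the motif than like background. Because the
six positions are independent under both the motif and the background
model, the *exact* distribution of the score of a background-drawn hexamer
can be computed by convolving the six per-position weight distributions,
which gives every match an exact p-value
$P(\text{score} \ge t)$. Candidate elements are extracted from 13-nt
regions (wide enough to absorb uncertainty in the annotated element
position) by taking the best-scoring window and keeping it when its
p-value clears $\alpha = 0.05$.

**Stage 2 — regression of log strength.** For a training set of promoters
with measured activities normalized to a reference (values in $(0,1]$), the
two scores form the feature space of

$$\ln(\text{strength}) = \beta_0 + \beta_{35}\,s_{35} + \beta_{10}\,s_{10} + \varepsilon.$$

The log link is not a convenience: strengths span orders of magnitude, and
the additive energy-like contribution of each element to the
polymerase–DNA interaction is expected to act multiplicatively on the
initiation rate. The response is floored at $10^{-4}$ before the log so
that promoters reported as inactive do not map to $-\infty$. Because the
normalization of strengths is multiplicative, rescaling all strengths by a
constant changes only the intercept (by the log of the constant), never
the slopes — a property the test suite checks.

## Fitting: exact and iterative

`fit_ols()` solves the least-squares problem exactly by QR decomposition,
and `model_stats()` supplies the classical inference: coefficient standard
errors from the residual variance and the inverse Gram matrix, t-tests and
confidence intervals on $n - m - 1$ degrees of freedom, the overall F-test,
and

$$\text{adj. } R^2 = 1 - (1 - R^2)\,\frac{n-1}{n-m-1}.$$

`fit_gradient_descent()` minimizes the same cost
$J(\beta) = \frac{1}{2n}\sum_i (x_i^\top\beta - y_i)^2$ by fixed-step batch
updates from zero-initialized coefficients. The default step size 0.015
with at most $10^5$ iterations converges on the training data without any
feature standardization (the score scales are moderate and the problem is
well conditioned); a `feature_scaling` flag standardizes the features for
harder problems and maps the coefficients back to the raw scale. Divergence
is detected as 100 consecutive cost increases and reported as an error
suggesting a smaller rate or scaling. On the shipped training set the two
fitters agree: fitted values correlate above 0.998 (in fact the gradient
coefficients match the exact ones to ~10⁻¹³), which the acceptance tests
assert.

The inference deliberately uses plain OLS theory — no robust or sandwich
errors — because the published interval estimates it must reproduce come
from that theory, and with $n = 18$ the data would not support anything
richer.

## Training data

The embedded training set (`anderson_fixture()`) is the 18-member Anderson
library of constitutive *tet* promoter variants, with activities normalized
to the strongest member and spanning (0.01, 1]. Each row also carries the
published PWM feature scores of its hexamers. Those printed scores are used
verbatim for everything regression-side, for a deliberate reason: the exact
parameterization (log base, pseudocount magnitude) of the original
RegulonDB-derived matrices behind them is not recoverable, so scores
recomputed from any rebuilt PWM would differ by an affine-ish
transformation and the regression coefficients would not be comparable
digit-for-digit. Splitting the package's claims this way keeps the
regression results exactly reproducible while the PWM machinery is
validated by exhaustive-enumeration properties instead.

One published number is knowingly inconsistent: the full-data predicted log
strength printed for BBa_J23110 does not follow from that promoter's own
printed scores under the published coefficients (they give −1.74, not
−3.39, and the corresponding cross-validation row agrees with −1.79). The
row-wise reproduction test therefore covers the other 17 promoters.

## Validation machinery

* **Leave-one-out cross-validation** (`loocv()`) refits the model $n$
  times, each time predicting the held-out promoter. The explicit refits
  are cross-checked in the tests against the closed-form OLS identity
  $e_{(i)} = e_i/(1 - h_{ii})$ with $h$ the hat-matrix diagonal.
* **Random-promoter baseline** (`random_baseline()`): hexamer pairs drawn
  uniformly over the alphabet are scored and predicted; per-set mean
  strengths over 100 sets of 100 give a sampling distribution whose grand
  mean and standard error (sd of set means / √sets) summarize how weak the
  model believes non-promoter sequence to be. "Random promoters" are
  represented directly as hexamer pairs because the model consumes nothing
  else.
* **Variant models** (`fit_variant_models()`): the interaction model
  $s_{35} * s_{10}$, the univariate combined-score model, and the
  raw-strength (un-logged) response model, reported side by side. On the
  training data the additive log model wins: the interaction term is
  nowhere near significance, and the raw-strength response costs ~0.25 of
  adjusted R² — the logarithmic link is doing real work.
* **Diagnostics** (`diagnostics()`): the four standard plot datasets
  (residual vs fitted, scale-location, normal Q-Q with plotting position
  $(i - 0.5)/n$, residual vs leverage) emitted as a table; standardized
  residuals are internally studentized.

## Synthetic data: what it emulates and what it does not

`sigma70_profile()` and `generate_hexamer_set()` stand in for a curated
promoter-element collection. Each profile gives the consensus base a
per-position probability patterned on the familiar σ⁷⁰ conservation
gradient — for TTGACA, (0.70, 0.78, 0.60, 0.55, 0.52, 0.55); for TATAAT,
(0.78, 0.76, 0.55, 0.55, 0.52, 0.82), i.e. the 5′ dinucleotides and the
final −10 T strongly conserved, the middle degenerate — with the remaining
mass spread evenly over the other three bases. Positions are sampled
independently. Real promoter collections violate that independence
(neighbouring positions co-vary, and element quality correlates with spacer
length, which this package deliberately does not model), so passing tests
on synthetic sets demonstrate correctness of the machinery, not biological
calibration of any particular PWM. Sizes used in the tests (hundreds to a
thousand hexamers, region sets of 50–2000) are comfortably past the point
where count noise dominates.

## Numerical choices

* **Log base 2** for the weights, recorded on the PWM and configurable;
  scores are bits-like and the choice only rescales the regression slopes.
* **Pseudocount mass 1 per position**, split proportionally to background.
* **Score-distribution granularity**: support points closer than
  $10^{-9}$ score units are merged during the convolution. Six positions
  give at most $4^6 = 4096$ distinct sums, so this is effectively exact —
  the tests require agreement with full enumeration to $10^{-6}$ — while
  keeping the representation canonical; the width is configurable for
  coarser, faster grids on longer motifs.
* **Ties in the window scan** go to the smallest offset, making extraction
  deterministic.
* **Strict inequality** (p < α) for significance filtering.
* **Degenerate inputs**: ambiguity codes and RNA bases are rejected rather
  than redistributed; empty sequence sets, rank-deficient designs, fewer
  than 4 training rows, and zero residual variance are explicit errors or
  warnings rather than silent NaNs.
* **Consensus bootstrap**: because the very first extraction pass predates
  any PWM, a Hamming-distance matcher against a literal consensus
  (mismatch penalty −1 per position) is provided; a single
  extract-filter-rebuild pass follows. No iterative refinement of the PWM
  is performed — one pass matches the intended dataset-construction flow,
  and iterating would change the dataset definition.

## Limitations

The model sees only the two hexamers: spacer length, UP elements, extended
−10 motifs, supercoiling and context effects are all outside its feature
space, and predictions for promoters whose strength depends on those
features will be off in ways the diagnostics cannot flag. Predicted
strengths above 1 simply mean "stronger than the reference" and are
reported as-is. The regression is trained on 18 promoters measured in one
reporter system; transferring the absolute scale to other systems relies on
the normalization argument above holding, which is exact only for the
intercept.
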