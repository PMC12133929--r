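---
title: "Dynamic influence inflation: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic influence inflation: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(didi)
```

## The problem

Functional connectivity methods for EEG — phase locking, coherence,
Granger causality — estimate a statistic over a time window, so their
temporal resolution is bounded by the window length (rarely below one
second in practice).  They also describe connectivity in general, with no
way to ask *which* connections drive a particular cognitive
differentiation.  This package takes a different route: instead of
compressing the recording into connectivity statistics, it **inflates** it
into a redundant representation whose components are directed,
per-sample influence signals, classifies that representation, and reads
the connections that matter for the classification back out of the
classifier's gradients.  The result is a directed connectivity description
at the native sampling rate, specific to the contrast being classified.

## The decomposition

For each channel $x_i$ an autoregressive model of order $N$ is fit by
ordinary least squares:

$$x_i(t) = \sum_{n=1}^{N} a_i(n)\, x_i(t-n) + \varepsilon_i(t),$$

where the residual $\varepsilon_i$ — the *innovation process* — is the
unpredictable part of the channel.  For every ordered pair (influenced $i$,
influencing $j$) the innovation is then regressed on the influencing
channel's history:

$$\varepsilon_i(t) = \sum_{n=1}^{N} b_{ij}(n)\, x_j(t-n) + \varepsilon_{ij}(t),$$

and the **directed influence signal** is the explained part,

$$c_{ij}(t) = \varepsilon_i(t) - \varepsilon_{ij}(t).$$

The univariate coefficients $a_i$ are deliberately *not* refit in the
second stage.  Granger causality in its classical form compares the
univariate residual variance with that of a free bivariate fit in which
the autoregressive coefficients may shift; keeping them fixed makes
$b_{ij}$ interpretable as a regression of the innovation itself on the
influencing channel, and makes two identities exact by construction:

* reconstruction: $x_i(t) = \sum_n a_i(n)x_i(t-n) + \varepsilon_i(t)$ at
  every fitted sample;
* decomposition: $\varepsilon_i = c_{ij} + \varepsilon_{ij}$ for every
  pair.

Because the pair regression is least squares on the same segment,
$\operatorname{var}(\varepsilon_{ij}) \le \operatorname{var}(\varepsilon_i)$
in sample, so the derived Granger causality
$\mathrm{GC}(i \leftarrow j) = \log \operatorname{var}(\varepsilon_i) /
\operatorname{var}(\varepsilon_{ij})$ is always nonnegative.  These three
facts are asserted to machine precision in the test suite — they are
algebra, not approximations.

### Relation to the free bivariate fit

Under exact system linearity the constrained and free bivariate residuals
coincide; in finite samples they coincide only when the two lag blocks
(own history, influencing history) are orthogonal.  `bivariate_gc()`
implements the free fit, and the test suite compares the two estimators on
instances with independently simulated channels and an injected lagged
coupling, where the blocks are near-orthogonal: over 50 such instances
(two channels, 2000 samples) the relative gap stays under 10%, with a
median near 2%.  When the influencing channel is strongly autocorrelated
the blocks correlate through the coupling itself and the gap grows — a
systematic finite-sample property of the constrained recipe, not a bug;
users comparing against classical GC on strongly autocorrelated data
should expect small discrepancies of this kind.

### Model order, demeaning, variances

* **Order $N$**: chosen so $N/f_s$ spans roughly 100–200 ms of history
  (the conventional compromise between temporal context and stability);
  at 160 Hz that gives the default $N = 20$.  Fits warn when fewer than
  $10N$ samples are available.
* **Demeaning**: each channel is demeaned over the fitted segment before
  fitting; the regressions carry no intercept.
* **Estimator**: OLS on the lag design via QR (`lm.fit`).  Yule–Walker is
  avoided: its small-sample bias would leak systematic structure into the
  innovations.
* **Variances**: population variances (mean of squares over valid
  samples), which is what makes the in-sample monotonicity exact.  A
  degenerate (constant) channel makes the lag design rank-deficient and is
  reported by name rather than silently regularized.

### Startup samples and context

$\varepsilon$ and $c$ are undefined for $t \le N$.  Epochs are therefore
extracted with $N$ pre-event *context* samples so the decomposition covers
the full analysis window; when no context is available the first $N$
output samples are dropped — never zero-padded, since padding would inject
an artificial transient exactly where event-locked analysis looks.
Models can be fit per epoch (`inflate_epoch()` with `models = NULL`) or
once per continuous recording and applied to epochs
(`didi(..., scope = "recording")` + `predict()`); the choice is recorded
in the output metadata.  Per-recording fitting maximizes the samples
behind each coefficient; per-epoch fitting lets the models track slow
nonstationarity.  Both are supported because neither dominates in
principle.

## The inflated array and its layout

Innovations and influence signals are collected into an
$M \times M \times T'$ array — $\varepsilon_i$ on the diagonal,
$c_{ij}$ at $(i, j)$ — and flattened to $M^2 \times T'$ for the
classifier, row $(i-1)M + j$ carrying component $i \leftarrow j$
(influenced-major).  Which of the two channel dimensions varies fastest is
immaterial to learning, so the bijection is simply frozen and written into
a JSON sidecar (`write_index_map()`) with channel names per row, so a
saliency row is always decodable without the originating session.  The
round trip is property-tested for $M \in \{2, 3, 19\}$.

Note the representation is deliberately redundant: the connectivity
information extracted into $c_{ij}$ is still present, unextracted, in the
accompanying $\varepsilon_i$.  The innovations are kept because the
influence signals alone cannot reconstruct electrode-local processes, but
the redundancy means a classifier *may* lean on the innovation rows even
when the influence rows carry the same information.

## The classifier

A compact convolutional network in the EEGNet family: a temporal
convolution whose kernel spans about half a second (default
$f_s/2$ samples, forced odd so same-padding is symmetric), a depthwise
"spatial" convolution across all input rows, a separable convolution
(depthwise temporal + pointwise), average pooling after the second and
third stages, and a dense softmax head.  ELU activations throughout;
dropout after each pooling stage; Adam on softmax cross-entropy.

The network is implemented in base R with a hand-derived backward pass.
Two things motivated this: the explanation stage needs the exact gradient
of a class score with respect to the input, and a self-contained
implementation keeps the whole pipeline inspectable.  The backward pass is
verified against central finite differences in the test suite (relative
error below $10^{-7}$ on random cells).  Batch normalization of the
original architecture is omitted: at the data scales this package targets
its estimates of batch statistics are noisier than the regularization is
worth, and per-channel input standardization covers the scale problem.
Standardization statistics (mean and sd per input row) are computed on the
training set only and stored in the model — influence signals span orders
of magnitude across pairs, and evaluation data never touch these
statistics.

Training is deterministic given the configuration seed (initialization,
shuffling and dropout all draw from one seeded stream), which the tests
assert by retraining.  No meta-parameter search is performed anywhere in
the package; the defaults follow the cited architecture family's
recommendations, with kernel sizes adapted to the sampling rate.

## Explanation

A **saliency map** is the elementwise magnitude of the gradient of the
target class's *pre-softmax* score with respect to the classifier input.
Two conventions matter:

* **Logit, not probability**: the softmax saturates once the model is
  confident and its gradient vanishes; the logit keeps a usable signal.
* **Network-input scale**: the gradient is taken with respect to the
  standardized tensor the network actually consumes.  Chaining through the
  standardization onto the raw scale would multiply each row by $1/sd$,
  systematically inflating the apparent importance of low-variance
  components (the near-zero chance-level influence rows) — an artifact,
  not importance.  `input_gradient()` exposes both scales; `saliency_map()`
  uses the network-input scale.  Signed maps are available behind a flag
  for users who care about direction of effect rather than importance.

A column of the saliency map, reshaped back through the frozen layout,
is a **connectivity support matrix** for that instant: off-diagonal cells
support directed connections, diagonal cells support electrode-local
processes.  Averages over an interval (`support_avg()`) give condensed
maps; the full-range average is the static support map used when no
temporal reference exists.  Interval boundaries are user-supplied —
automatic changepoint detection is out of scope.  Support matrices render
onto the bundled 19-electrode 10-20 montage as arrow maps (`top_k`
arrows, default 20, keeps maps legible; widths normalized to the maximum
displayed value), and saliency maps export as globally normalized PNG
frame sequences for video assembly with any external encoder.

## The synthetic validation surface

Real EEG ground truth for directed, time-switching coupling does not
exist, so the package validates against simulated vector autoregressions
with planted couplings (`simulate_var()`, `make_switching_dataset()`).
The generator emulates exactly the property the method claims to recover —
a directed interaction that switches on inside a sub-window of each epoch
— and nothing else: Gaussian innovations, no 1/f spectra, no volume
conduction, no forward modelling.  Passing tests therefore demonstrate
correctness of the estimators and the localization machinery, not
robustness to the full physics of scalp EEG.

Study conditions for the reference experiment (`switching_benchmark()`),
chosen once as a minimal but realistic stand-in for an event-locked task:

* 3 channels, base VAR(1) with diagonal 0.5, unit Gaussian innovations,
  64 Hz, 2 s epochs (128 samples);
* planted coupling $1 \leftarrow 2$, lag 1, gain 0.8, active from 0.5 s to
  1.5 s (samples 33–96); 50 epochs per class; every epoch an independent
  realization with a $10K$-sample burn-in;
* analysis order $N = 8$ (125 ms at 64 Hz), per-epoch fitting, with 8
  context samples attached so the decomposition covers the full epoch;
* classifier: 4 temporal filters $\times$ depth 2, 8 separable filters,
  dropout 0.25, Adam at $2\times10^{-3}$, batch 16, 150 passes over a
  70/30 split.  150 passes is a convergence choice: partially trained
  networks on this problem classify above chance but spread their
  gradients across rows, and the localization claim is about the
  *converged* model's focus.

The benchmark measures held-out accuracy (binomial-tested against chance)
and whether the planted pair's row carries more mean in-window saliency
than every other off-diagonal row.  With the gain set to zero the two
classes are statistically identical and accuracy must stay inside the
chance interval — the standard leakage control.  A stationarity guard
rejects coupling gains that destabilize the companion matrix; note that a
purely unidirectional coupling on a diagonal base can never destabilize it
(the companion matrix stays block-triangular), so that guard only binds
when the base process already contains a feedback path.

## Numerical and degenerate-input policy

* Non-stationary simulation specs are rejected at construction with the
  offending spectral radius.
* Too-short signals, rank-deficient lag designs, mismatched lengths,
  nonpositive variances, unknown channels and unknown class labels all
  raise errors naming the offender; nothing is silently padded, clipped or
  regularized.
* Sliding-window GC warns when the window drops below $10N$ samples
  rather than refusing — the volatile estimates are themselves
  informative, and reproducing the window-length trade-off (estimate
  variance falling as windows widen) is part of the validation suite.
* All randomness flows through explicit integer seeds; identical seeds
  reproduce datasets bit-for-bit and training histories exactly.

## Problem sizes used in validation

The test and acceptance workloads run on a single CPU: coefficient
recovery uses $T = 50{,}000$ single simulations; direction detection 100
simulations at $T = 4000$; oracle comparison 50 instances at $T = 2000$;
windowed-GC behavior 100 simulations at $T = 2000$; the end-to-end
benchmark 10 seeds (plus one null run) of the reference experiment above.
These sizes were picked so each statistical claim has enough replication
to be stable under reseeding, while the full suite stays comfortably
interactive.

## Known limitations

* Bivariate only: no conditional (multivariate) or spectral GC; influence
  signals for pair $(i,j)$ do not partial out other channels.
* The inflated representation is redundant (see above); a classifier may
  attribute to innovation rows what influence rows also carry.  The
  benchmark shows the converged compact network prefers the extracted
  form, but this is an empirical, task-dependent observation.
* Explanations inherit the classifier's quality: saliency from a model at
  chance is noise.  Check accuracy before reading maps.
* The EDF reader covers plain EDF with uniform sampling rates; EDF+
  annotation parsing and other acquisition dialects are not implemented.
* Rendering and frame export are schematic (2D standard positions), not
  anatomically projected.
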