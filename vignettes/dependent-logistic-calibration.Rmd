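---
title: "Dependent logistic calibration of detection confidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dependent logistic calibration of detection confidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(detcal)
```

## The problem

An object detector scanning coronary OCT frames for calcified plaque emits,
per frame, a set of boxes with confidence scores. A detector is *calibrated*
when those scores mean what they say: among all predictions stated at
confidence $c$, a fraction $c$ are correct. Modern detectors usually are
not — they are overconfident — and in an interventional-cardiology workflow
an inflated confidence is worse than a missing one. detcal measures that
bias and removes it post hoc, without touching the detector.

Everything downstream needs a definition of "correct". A prediction is
correct ($z = 1$) when it can be matched to a same-class ground-truth box in
the same image with IoU at or above a threshold. Matching is greedy in
descending confidence with at most one detection per ground truth, the
standard evaluation semantics: it is deterministic, auditable, and on small
scenes it agrees with exhaustive assignment search (this is one of the
package's property tests). Counts of matched/unmatched predictions and
ground truths give TP, FP, FN and hence precision, recall and F1.

## Measuring miscalibration

The expected calibration error bins the stated confidence $\hat p$ into $M$
equal-width bins $B_m$ and averages the gap between each bin's empirical
precision and its mean confidence:

$$\mathrm{ECE} = \sum_{m=1}^{M} \frac{|B_m|}{N}
  \left| \mathrm{Prec}(m) - \overline{\mathrm{conf}}(m) \right|.$$

Choices made here, and why:

* **$M = 10$ by default.** The dominant convention in the calibration
  literature; exposed as a parameter since ECE is mildly $M$-dependent.
* **Last bin closed.** Bins are $[0, 1/M), \dots, [(M-1)/M, 1]$ so that
  confidence exactly 1.0 is binned rather than dropped.
* **Binning uses confidence only.** Box features affect the calibration
  *map*, not the ECE definition, which remains a single scalar per model.
* **Empty bins contribute zero**; empty record sets are an error rather
  than ECE 0, since an undefined quantity should not masquerade as a
  perfect one.
* **Records pool across classes.** The calcification task is single-class;
  for multi-class streams, compute per-class ECE by subsetting records.

ECE is a noisy estimator: with $N$ records and $M$ bins, per-bin precision
carries binomial error of order $\sqrt{M/N}$, which sets a noise floor of
roughly 0.01 at $N = 2\times10^4$, $M = 10$. Differences below that floor
between two calibration methods are not resolvable at that sample size.

## The calibration map

Score-only recalibration (Platt scaling, histogram binning, temperature
scaling) conditions on the confidence alone. Detection adds usable context:
where the box is. Miscalibration in OCT detection can be
position-dependent — e.g. systematically worse near the catheter shadow or
at larger imaging depth — so the calibrator here consumes the feature
vector

$$s = (\mathrm{logit}\,\hat p,\; c_x,\; c_y),$$

with $c_x, c_y$ the box center normalized by image width and height into
$[0,1]$. Correct and incorrect predictions' feature vectors are modelled as
multivariate Gaussians $\mathcal N(\mu_+, \Sigma_+)$ and
$\mathcal N(\mu_-, \Sigma_-)$, estimated by sample means and covariances
(denominator $n-1$) of the two populations in a fit split. The calibrated
confidence is the sigmoid of the Gaussian log-likelihood ratio

$$\mathrm{lr}(s) = \tfrac12\left[(s-\mu_-)^\top \Sigma_-^{-1}(s-\mu_-)
  - (s-\mu_+)^\top \Sigma_+^{-1}(s-\mu_+)\right] + c, \qquad
  g(s) = \frac{1}{1 + e^{-\mathrm{lr}(s)}}.$$

This is exactly the posterior $P(z=1 \mid s)$ when the two populations are
truly Gaussian — a property the test suite exploits by fitting on samples
from known Gaussians and comparing against the closed form. Because
$\Sigma_+$ and $\Sigma_-$ are estimated separately the map is quadratic in
$s$ (a quadratic-discriminant calibrator); with equal covariances it
degenerates to an affine-in-$s$ logistic model.

Design decisions that were genuinely open:

* **The constant $c$.** Taken as
  $c = \tfrac12 \ln(\det\Sigma_-/\det\Sigma_+) + \ln(n_+/n_-)$ — the exact
  normalizing constant of the Gaussian log-likelihood ratio including the
  prior log-odds of the two populations, validated in tests against an
  independent explicit-density computation. `include_prior = FALSE` drops
  the $\ln(n_+/n_-)$ term for the strict equal-prior ratio.
* **Sign convention.** "+" is the correct population throughout, so large
  `lr` means high calibrated confidence.
* **Logit-transformed confidence** (default on, `logit_conf = FALSE` to
  disable). A variable bounded in $[0,1]$ is a poor Gaussian; its logit is
  much better behaved. The transform clips to $[\varepsilon, 1-\varepsilon]$
  with $\varepsilon = 10^{-6}$ first, bounding the feature at
  $|\mathrm{logit}| \le 13.8$.
* **Ridge regularization.** Each covariance receives
  $\lambda I$ with $\lambda = 10^{-6}\,\mathrm{tr}(\Sigma)/d$, guaranteeing
  positive-definiteness for near-degenerate populations while perturbing
  well-conditioned fits negligibly.
* **Numerics.** Quadratic forms and log-determinants go through Cholesky
  factors (`chol`/`backsolve`); no covariance is explicitly inverted.
* **Fit/test protocol.** 60% of prediction records fit the calibrator, 40%
  are held out, via a seeded shuffle (optionally stratified by $z$ to one
  record per stratum). Missed ground truths have no confidence and never
  enter calibration.
* **Minimum population sizes.** With $d$ features, each population must
  contribute at least $d + 1$ records for a full-rank covariance; fitting
  errors name the deficient class.

## What the simulator emulates — and what it does not

`simulator_config()` / `generate_dataset()` produce ground-truth boxes and
a detection stream with controllable miss rate, per-image false-positive
rate, localization noise, and confidence distributions (Beta-distributed;
low-mean for clutter). Correctness is labelled in one of two modes:

* **`iou_labeled`** — detections are actually matched to the simulated
  ground truth, exactly as a real pipeline would; the full stack
  (IO → matching → records → ECE) is exercised.
* **`posterior_driven`** — correctness is drawn from a stated logistic
  truth
  $P(z=1 \mid s) = \sigma(a_0 + a_\mathrm{conf}\,\mathrm{logit}(\hat p)
  + a_{cx}(c_x - 0.5) + a_{cy}(c_y - 0.5))$,
  available exactly through `true_posterior()`, enabling quantitative
  recovery tests.

The defaults are the study conditions used throughout the tests and the
acceptance script: images of 1024 × 1500 px (an OCT B-scan cross-section),
a Poisson(2) ground-truth count per image, box sides uniform in 80–300 px,
10 px localization noise, 15% miss rate, Poisson(0.7) false positives per
image, `Beta(5, 2)` confidences for detections of real objects and
`Beta(2, 5)` for clutter, and truth coefficients
$a_0 = -1$, $a_\mathrm{conf} = 0.5$, $a_{cx} = 2$, $a_{cy} = 0$. Those
coefficients make the stream overconfident (ECE ≈ 0.25 before calibration)
*and* position-dependent, so a dependent calibrator has something a
score-only calibrator cannot capture; the $a_{cx}$ term is on by default
for exactly that reason. Identical `(config, seed)` pairs reproduce the
dataset bit for bit, and the generator restores the ambient RNG state.

What passing tests on this stream do **not** show: the simulator draws box
geometry independently of appearance (there are no images behind the
boxes), its confidence marginals are Beta by fiat, and its miscalibration
is exactly logistic in $(\mathrm{logit}\,\hat p, c_x, c_y)$. Real
detectors' miscalibration need not live in that family, real correctness
probabilities are coupled to image content, and detection errors cluster in
ways the independent-noise model does not reproduce. Results on synthetic
streams demonstrate correctness of the machinery and the *direction* of the
calibration effect, not clinical performance.

## Problem sizes and tolerances used in the tests

The suite validates, among others: ECE against a naive double-loop oracle
to $10^{-12}$ (100 random record sets, $N \le 1000$, $M \in \{5,10,15\}$);
near-zero ECE ($\le 0.01$) for a perfectly calibrated stream of $10^5$
records; recovery of a known 3-D Gaussian posterior to mean absolute error
$\le 0.01$ (50,000 samples per class) with the constant $c$ within 0.05 of
its closed form; the log-likelihood ratio against an explicit two-density
oracle to $10^{-9}$; and, on the default overconfident stream of ~50,000
detections with a 60/40 split, a held-out ECE reduced by at least half in
at least 9 of 10 seeds, with the $(conf, c_x, c_y)$ calibrator beating the
confidence-only variant in at least 9 of 10. The last comparison operates
near the ECE noise floor discussed above, which is why it is stated over
seeds rather than as a per-seed guarantee.

## Augmentation

Two operators, chosen for OCT physics:

* **Motion blur** — convolution with a normalized anti-aliased line kernel
  (length $L$ px, odd, default 9; angle in degrees, default 0; tent-profile
  anti-aliasing across the perpendicular direction), emulating
  catheter/vessel motion during acquisition. Borders use edge replication
  to avoid a darkened rim. A constant image is exactly invariant and
  interior intensity is conserved.
* **Horizontal flip** — columns reversed and each box mapped to
  $(W - x_\max,\, y_\min,\, W - x_\min,\, y_\max)$; an exact involution.

Vertical flips and rotations are deliberately not provided: OCT light
propagates in a fixed direction, and such transforms would produce frames
that cannot occur.

## Known limitations

* The calibrator assumes class-conditionally Gaussian features. When the
  true log-likelihood ratio is affine (as in the simulator's
  posterior-driven truth), the quadratic fit retains a small
  misspecification residual (~0.013 ECE against the latent truth at the
  default conditions) — visible only below the sampling noise floor.
* Single operating point: no PR-curve or mAP sweeps over IoU thresholds.
* One calibrator per class is the intended use; the package does not bundle
  a multi-class calibrator container.
* ECE here is the standard equal-width-bin estimator; no adaptive binning,
  maximum calibration error, or Brier score.
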