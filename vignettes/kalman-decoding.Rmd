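---
title: "Kalman decoding of finger kinematics from surface EMG: model, training, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kalman decoding of finger kinematics from surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgkalman)
```

## The decoding problem

Proportional myoelectric control asks for continuous joint-angle
trajectories, not discrete gesture labels. `emgkalman` treats the six
finger-joint angles $x_k \in \mathbb{R}^6$ (thumb flexion, thumb abduction,
and index/middle/ring/little flexion, in degrees) as the state of a
discrete-time linear-Gaussian dynamical system, and the vector of windowed
sEMG amplitude features $z_k \in \mathbb{R}^{16}$ as its observation:

$$x_{k+1} = A x_k + w_k, \qquad w_k \sim N(0, W)$$
$$z_k = H x_k + v_k, \qquad v_k \sim N(0, Q).$$

The premise is physiological: within the operating range, the amplitude
envelope of a surface EMG channel grows roughly linearly with the
excursion of the joints driven by the underlying muscles, so a linear
observation map is a reasonable first-order model. The state equation
encodes the smoothness of finger motion at the window step scale (25 ms):
angles change little between adjacent steps, so $A$ is close to, but not
exactly, the identity.

All four parameters are fitted in closed form from synchronized training
data, and decoding is the classical Kalman predict/update recursion —
which is why training takes milliseconds where iterative regression or
network training takes minutes.

## Preprocessing

Raw sEMG is bandpass-filtered (Butterworth, 10–450 Hz) and segmented with
a sliding window of 150 ms advanced by 25 ms (300 and 50 samples at
2 kHz). Each window yields one observation vector — the mean absolute
value (MAV) per channel — and one state vector: every DOF's angle at the
window's **last** sample. Sampling the angle at the trailing edge while
the MAV integrates the preceding 150 ms lets the window itself absorb the
electromechanical delay (EMG leads motion by roughly 30–150 ms); no
explicit lag shift is applied.

Numerical conventions, fixed to remove off-by-one ambiguity:

* windows are 0-based half-open intervals $[s, s+300)$; the "last value"
  is the sample at index $s + 299$;
* an incomplete tail window is dropped, never padded, so the window count
  is exactly $\lfloor (N - 300)/50 \rfloor + 1$;
* feature extraction is done per session and concatenated afterwards
  (`bind_training_pairs()`), so no window straddles a recording boundary.

The filter order (4) is a choice, not a given: it is the common default
for offline sEMG work. Filtering is zero-phase (forward–backward) by
default for offline analysis; `zero_phase = FALSE` gives the causal
forward pass a streaming implementation would use.

## Closed-form training

With $X_1 = [x_1 \ldots x_{M-1}]$, $X_2 = [x_2 \ldots x_M]$ the
least-squares solutions are

$$A = X_2 X_1^\top (X_1 X_1^\top)^{-1}, \qquad
  H = Z X^\top (X X^\top)^{-1},$$

and the noise covariances follow from the residuals:

$$W = \tfrac{1}{M-1}(X_2 - A X_1)(X_2 - A X_1)^\top, \qquad
  Q = \tfrac{1}{M}(Z - H X)(Z - H X)^\top.$$

Three numerical decisions sit around these formulas:

* **Centering** (`center = TRUE`, the default). The model has no
  intercept, but MAV is strictly positive and a resting hand has nonzero
  joint angles, so the raw matrices violate the zero-mean assumption
  structurally. Training therefore subtracts the training-set row means of
  $X$ and $Z$ before fitting; the filter runs in centered coordinates and
  adds the state mean back on output. The flag is exposed because the
  uncentered fit is still well defined (and appropriate for zero-mean
  simulated data).
* **Regularization.** Sixteen MAV channels are often collinear, so each
  Gram matrix $G$ receives a relative ridge
  $\texttt{ridge} \cdot \mathrm{tr}(G)/\dim \cdot I$ (default
  $10^{-8}$) before a Cholesky solve; if the matrix is still numerically
  rank-deficient the fitter warns with the reciprocal condition number and
  falls back to a pseudoinverse. A state row with zero variance (a DOF
  that never moves) is reported by a warning — its row of $A$ is not
  identifiable.
* **PSD repair.** Finite-sample residual covariances can be numerically
  indefinite; $\hat W$ and $\hat Q$ are symmetrized and eigenvalue-clipped
  at zero on store.

## Decoding

The recursion alternates prediction,
$\hat x^-_k = A\hat x_{k-1}$, $P^-_k = A P_{k-1} A^\top + W$, and update
with gain $K_k = P^-_k H^\top (H P^-_k H^\top + Q)^{-1}$. Implementation
choices:

* the innovation covariance is factorized by Cholesky, never inverted
  explicitly; on failure a single jitter of $10^{-10}\,\mathrm{tr}(S)/m$
  is added, after which the step fails loudly with a conditioning report;
* $P$ is symmetrized after every step because the textbook update
  $(I - K H)P^-$ loses symmetry in floating point; a Joseph-form update is
  available behind `joseph = TRUE` for ill-conditioned systems;
* initialization is not dictated by the training equations, so it is a
  design choice: $\hat x_0$ is the training mean state (zero in centered
  coordinates) and $P_0$ the empirical covariance of the centered training
  states — a diffuse but data-scaled start whose influence decays within a
  few steps;
* `kf_predict()`/`kf_update()` are pure single-step functions so a caller
  can drive the decoder window by window in real time; `run_filter()` is
  the batch wrapper and is fully deterministic.

Accuracy is summarized by the Pearson correlation coefficient per DOF
between decoded and measured angle trajectories, computed on the
window-step time base (one value per 25 ms, since estimates only exist
there). A zero-variance sequence makes the coefficient undefined; the
evaluator returns an explicit `NA` and excludes that DOF from the
mean ± sd aggregate, with a warning — never a silent zero.

## What the synthetic generator emulates — and what it does not

`generate_session()` produces the data structure the decoder assumes,
with every deviation from real recordings being a *simplification in the
model's favor*:

* angles follow raised-cosine flexion/extension events around a nonzero
  rest posture (15° by default, so centering is actually exercised), with
  a round-robin single-DOF movement plan by default — individual finger
  movements separated by rest, several repetitions per DOF per minute;
* each EMG channel is 10–450 Hz band-limited Gaussian noise whose
  amplitude envelope is `baseline + gains %*% excursion` — the linear
  amplitude–angle premise is true by construction. Gains are drawn once
  per (channel, DOF): each channel is dominated by one DOF
  (round-robin, gain 0.7–1.0) with weak crosstalk (≈0.15 scale) from the
  others, mimicking electrodes over distinct muscles; a uniformly mixed
  gain matrix would make the observation map ill-conditioned in a way a
  sensible electrode montage is not;
* additive sensor noise at `noise_scale` (default 0.05) of the baseline
  envelope amplitude.

Real sEMG adds what the generator deliberately omits: amplitude
nonlinearity and saturation, fatigue and electrode-shift nonstationarity,
motion artifacts, crosstalk that varies with posture, and day-to-day
variability. Passing the end-to-end tests therefore shows the pipeline is
a correct and stable implementation of the method under its own
assumptions — it does not predict the accuracy attainable on recorded
data, which is known to be substantially lower.

`simulate_lds()` is the second generator: an exact linear-Gaussian
simulator with user-supplied $(A, H, W, Q)$, used for parameter-recovery
and filter-equivalence experiments where ground-truth parameters must be
known.

## Problem sizes used in the shipped experiments

Parameter-recovery experiments run at the scale of one subject's training
data — 6 states, 16 observations, 45,000 window steps — where the
closed-form estimates land within ≈1–2% relative Frobenius error of the
generating parameters, and the closed-form solve itself takes on the
order of 10 ms. End-to-end decoding experiments use three one-minute
synthetic sessions at 2 kHz (2,395 windows each): train on two,
test on the held-out third, mirroring the train-on-datasets-1-and-2,
test-on-dataset-3 protocol used with recorded data. Oracle-equivalence
checks run on batches of 100 random systems with dimensions up to the
application's (n ≤ 6, m ≤ 16).

## Known limitations

* The linear observation model is first-order; no feature normalization
  or nonlinear envelope correction is applied (none is part of the
  method).
* Only the MAV feature is implemented; multi-feature variants (zero
  crossings, waveform length, slope-sign changes) are out of scope.
* $A, H, W, Q$ are time-invariant; no adaptive or EM refinement.
* No smoothing (RTS) pass — the decoder is causal by design, matching the
  real-time control setting.
* Recorded-data loading expects the plain-text dialect produced by the
  bundled converter; the six-DOF glove map ships as an editable JSON
  config (`inst/extdata/db8_dof_map.json`) because glove channel
  conventions vary across dataset releases.
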