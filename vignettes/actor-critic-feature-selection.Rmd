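---
title: "Actor–Critic feature selection for postoperative sepsis prediction: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Actor-Critic feature selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model, the
estimators behind the training loop, the numerical choices, and what the
synthetic experiments do and do not demonstrate.

## 1. The prediction problem

Postoperative sepsis is rare (about 5% of surgical cohorts) and its risk
signal is spread over heterogeneous sources: preoperative static
indicators (venous-blood biochemistry, coagulation markers, age, platelet
count; 20 variables here) and intraoperative monitoring series (heart
rate, systolic/diastolic pressure, oxygen saturation, central venous
pressure). The clinical premise is that *fluctuation* of vital signs
carries risk information: a patient whose intraoperative signals swing
widely is more likely to develop sepsis. Accordingly each series is
summarized by its mean and its **population** standard deviation (divisor
N, not N−1 — the definition is part of the method's contract and the test
suite pins it: the series 1,2,3 must give σ = √(2/3)). The 20 static plus
10 statistical features form the d = 30 vector `X_d` that the selection
machinery works on; the raw series are reserved for the baseline model.

## 2. The three networks

**Actor (selection network).** One self-attention block over the 30
feature positions. Each feature is a scalar token: query/key/value are
full-width linear maps, the attention logits are the outer product of the
per-instance query and key vectors with the conventional scaled
dot-product factor 1/√d, and the attended values are added back through a
residual connection. A final linear layer and elementwise sigmoid give
per-patient selection probabilities `S_d` strictly inside (0,1). Training
samples a Bernoulli mask `M ~ Bern(S_d)` element-wise; evaluation uses the
deterministic threshold `M = 1[S_d ≥ 0.5]` so reports are reproducible.
Masking is the Hadamard product — unselected features become exactly 0,
which in standardized coordinates is the cohort mean.

**Critic (prediction network).** Input linear 30→64, then three blocks of
{self-attention (residual), SiLU, linear 64→64, dropout 0.5 active only in
training}, then linear 64→1 with sigmoid. The Critic sees only masked
features; with the Actor near its uninformed state (S ≈ 0.5) this is
aggressive input dropout, which is the main reason the Critic generalizes
better inside the joint loop than when trained alone on full inputs.

**Baseline model.** A TCN of five residual blocks (two causal dilated
convolutions each: 10 conv layers; kernel 3; dilations 1,2,4,8,16; 32
channels; ReLU), average pooling (width 2, stride 2) after the second,
third and fourth blocks, and global average pooling over time. Left
padding replicates the first time step, so a series constant in time maps
to a T-independent embedding, and causality holds: no activation depends
on later inputs. The head concatenates static block, statistical block and
embedding into a 2-layer fully connected classifier. Its loss is
`L_fcl + L_hsic`.

## 3. HSIC regularization

The HSIC penalty measures statistical dependence between the standardized
statistical block and the TCN embedding of the same mini-batch, pushing
the TCN to encode temporal structure *beyond* what means and SDs already
capture. We use the standard biased empirical estimator
`(m−1)⁻² tr(K H L H)` with Gaussian kernels
`k(x,x′) = exp(−‖x−x′‖²/(2σ²))`; the population quantity is the squared
Hilbert–Schmidt norm of the cross-covariance operator and vanishes iff the
two variables are independent. Bandwidths come from the median heuristic
on the current batch (median pairwise distance; fallback 1 when degenerate)
and are treated as constants with respect to gradients — the penalty's
gradient flows only through the embedding Gram matrix. Batches of fewer
than two patients return 0 with a warning. The estimator is pinned to an
independent quadruple-sum oracle at small m, and a permutation test at
m = 100 separates dependent (Y = X² + noise) from independent pairs.

## 4. Losses, reward, and the Actor's gradient estimator

All logged quantities follow the printed algebra exactly, and the
identities are asserted at every step to 1e-9:

* `L_baseline = L_fcl + L_hsic`
* `R = −(L_prediction − L_baseline)`
* `L_critic = L_baseline + L_prediction`
* `L_actor = R·L_fs − λ·S̄_d`
* `L_total = L_actor + L_critic`

`L_fs` is the cross-entropy between `S_d` and the sampled mask — the
negative mean log-likelihood of the action. Minimizing `R·L_fs` with `R`
detached is therefore the classical REINFORCE score-function objective:
for positive reward it raises the log-probability of the sampled mask. A
`reward_sign` switch allows flipping the convention; the printed form is
the default and is already the standard policy-gradient direction.

Two estimator refinements matter in practice, and both leave the expected
gradient direction unchanged (patients are independent, and control
variates are independent of the scored draw):

1. **Instance-level credit** (`reward_level = "instance"`, default). The
   batch-level scalar `R` multiplied by the batch-mean score has the right
   expectation but √batch-worse signal-to-noise; crediting each patient's
   mask with that patient's own loss difference restores the variance an
   instance-wise method needs. The literal batch-scalar composition
   remains available (`reward_level = "batch"`), and the logged `R` is
   always the batch-level scalar.
2. **Self-critical, antithetic control variate**
   (`reward_control_variate = TRUE`, default). A second, independent mask
   draw is scored at the same Critic state (dropout off for both reward
   forwards, so dropout noise cannot pollute the reward), and the loss
   difference of the two draws drives a symmetric update applied where the
   draws disagree. Patient effects — e.g. the persistently large losses of
   the rare positives — and Critic drift cancel exactly. Without these two
   refinements the score signal is empirically drowned: selection
   probabilities either saturate uniformly or diffuse at chance.

**λ (selection incentive).** The `−λ·S̄_d` term *rewards* larger selection
probabilities. Under a normalized optimizer its constant-sign gradient
dominates the zero-mean score noise and saturates every probability at 1,
erasing the selection signal entirely (we observed S̄ = 0.998 uniformly
with λ = 0.1). The default is therefore λ = 0; `sweep_lambda()` and the
`sweep-lambda` CLI command exist to study the trade-off explicitly.

**Optimizers.** The protocol is 100 epochs, batch 32, initial learning
rate 0.01 multiplied by 0.95 per epoch after epoch 50 ("exponential decay
in the later stage"). Critic and baseline use SGD with classical momentum
0.9 — at this learning rate Adam oscillated, and at smaller rates it
memorized the training set with poor held-out discrimination. The Actor
uses Adam: its score-function gradient carries an intrinsic 1/(batch·d)
scale, and a scale-invariant optimizer lets it move at all under the
shared learning rate. Per-network optimizers are a configuration option;
`momentum = 0` gives plain gradient descent (used by the test that
verifies monotone full-batch convergence of the Critic alone).

## 5. The synthetic cohort generator

The generator emulates the shape of a real surgical cohort — default
n = 1538 with exactly 82 positives (~5.3%), 20 static indicators on
plausible scales, 5 vital-sign channels at T = 48 time steps (about four
hours of intraoperative monitoring at 5-minute resolution; the monitoring
duration is not part of the method's contract and is exposed as
configuration). Structure is planted as follows:

* Static indicators are independent Gaussians; a configurable subset
  (default: 5′-NT, Crea, Age, Na) is informative.
* A latent per-patient dispersion factor `u` inflates the innovation
  variance of the heart-rate AR(1) series (autocorrelation 0.8 around
  physiologic means, plus a small non-informative per-patient level
  shift), so the *standard deviation* of HR — the `HR_S` statistical
  feature — carries label signal, mirroring the premise that fluctuation
  predicts sepsis.
* The latent risk is linear in the standardized informative features and
  `u` (scaled by `effect_size`, default 2, against unit noise); the
  `positive_count` patients with the highest risk are labeled positive.
  Thresholding gives exact class counts, which the tests rely on;
  `effect_size = 0` severs the feature–label link (chance-level AUC).

What the generator does **not** emulate: correlated laboratory panels,
missingness mechanisms, non-stationary surgical phases, measurement
artifacts, site effects. Passing the recovery experiment therefore shows
the estimator can find planted low-dimensional structure at clinical
sample sizes and prevalence — not that the pipeline is robust to real EHR
pathology.

## 6. Numerical choices and degenerate inputs

* Cross-entropies clip probabilities at 1e-12; the Actor's gradient is
  taken at the pre-sigmoid logits, so saturated probabilities cannot blow
  up the selection-loss gradient.
* Zero-variance feature columns get scale 1 (with a warning) in the
  z-scaler; signal channels are z-scored per channel over patients and
  time, with scalers always fitted on training rows only.
* Median-heuristic bandwidth 0 (identical points) falls back to 1.
* Average pooling drops a trailing odd time step; global pooling divides
  by the pooled length.
* Missing CSV cells are median-imputed with a message; malformed files
  (duplicated patient/time rows, non-numeric cells, patients present in
  only one file) fail loudly with row context.
* Ties in the feature ranking break alphabetically; the split convention
  is `round(frac·n)` per stratum, clamped so no part is empty.
* Non-finite losses abort training and return the last completed epoch's
  checkpoint with a `diverged` flag.

## 7. Scale of the shipped experiments

The packaged experiments run on one CPU core. The recovery experiment
uses n = 2000 patients (100 positive), T = 48, three seeds of the full
100-epoch protocol; unit tests use cohorts of 60–200 patients with
T = 8–16 and a 12-epoch smoke fit. The attention and convolution kernels
are compiled (RcppArmadillo); everything else — linears, optimizers, the
training loop — is plain R, so a full 100-epoch run takes on the order of
two to three minutes.

## 8. Known limitations

* The ablation networks (feedforward selector/predictor, hidden width
  100) are smoke-tested for trainability, not tuned.
* The score-function estimator ranks features reliably but the absolute
  selection probabilities stay near 0.5 at these sample sizes; they are
  interpretable as a ranking, not as calibrated inclusion probabilities.
* Single-head attention only; no positional encodings (feature order is
  fixed by the contract).
* The Critic evaluates at the 0.5 mask threshold; patients whose
  informative features sit just below threshold lose them at evaluation
  time, which couples evaluation AUC to how decisively the Actor has
  separated the features.
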