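---
title: "Block-sparse Bayesian channel selection for P300 spellers: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-sparse Bayesian channel selection for P300 spellers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p300bsbl)
```

## The problem

A P300 speller decodes attended characters from EEG by detecting the
event-related potential that rare, attended stimuli evoke. Recordings use
many electrodes, but most channels contribute noise rather than signal for
a given participant, and a smaller montage is cheaper to prepare and less
prone to overfitting. Channel selection should therefore be automatic,
participant-specific and integrated with the decoding model rather than
fixed a priori.

This package treats selection as structured sparse regression. Each
stimulus yields a feature row built channel-major from `N_t` time samples
of each of `N_c` channels, with label +1 (target) or -1 (non-target). In
the linear model

$$y = Xw + \varepsilon, \qquad \varepsilon \sim \mathcal N(0, \sigma^2 I),$$

the weight vector splits into one block per channel,
$w = (w_1, \dots, w_{N_c})$, and each block gets the prior

$$w_b \sim \mathcal N\!\left(0,\; \gamma_b B_{re(b)}\right).$$

The scalar $\gamma_b \ge 0$ measures the channel's relevance: when it is
driven to zero the whole channel leaves the model. The matrix $B_{re}$
captures the correlation between the time-sample weights *within* a block
-- P300 features are band-passed and decimated, so neighbouring samples
are strongly correlated -- and is shared by all channels of a spatial
electrode region $re$ ("regional smoothing"), reflecting the volume
conduction that makes neighbouring electrodes behave alike.

## The EM engine

Fitting alternates a Gaussian posterior computation for $w$ with
closed-form updates of $(\sigma^2, \gamma, B)$:

* **Posterior.** Two algebraically equivalent routes: the direct form
  inverts a $D \times D$ matrix, the Woodbury form an $N \times N$ one.
  The engine picks whichever matrix is smaller (`choose_posterior_path()`),
  so the cost tracks `min(N, D)` as pruning shrinks the problem. The two
  routes agree to at least `1e-8` relative error (a property the test
  suite checks over random instances); the Woodbury route additionally
  tolerates zero-variance blocks since it never inverts the prior.
* **Noise variance.** The standard EM update from the residual plus a
  trace correction; `D` in that update counts the *currently active*
  features. The alternative (the original feature count) double-counts
  coordinates that no longer exist in the posterior; dimensional
  consistency decides, and this is flagged as a package choice.
* **Relevance.** $\gamma_b$ is the $B^{-1}$-weighted second moment of the
  block posterior divided by the block size, computed from the *previous*
  iteration's $B$.
* **Correlation.** Each region averages its blocks' normalized second
  moments (using the same-iteration $\gamma$), then the average is
  constrained to AR(1) Toeplitz form $[B]_{ij} = r^{|i-j|}$ with
  $r = m_1/m_0$, the ratio of the mean first sub-diagonal to the mean
  diagonal. $r$ is clamped to $|r| \le$ `ar_clamp` (default 0.98) because
  the empirical ratio can exceed 1 while the Toeplitz form is positive
  definite only for $|r| < 1$. A region whose blocks have all been pruned
  keeps its previous matrix.
* **Pruning.** After each iteration, blocks with $\gamma_b < \tau$ are set
  to exactly zero -- at most five per iteration (the practicality cap),
  smallest first, ties to the lower channel index -- and their columns are
  physically removed from the problem. Pruning is permanent.

Convergence is declared when the relative L2 change of the active
$\gamma$ vector drops below `tol` (default `1e-4`) in an iteration that
pruned nothing; `max_iter` (default 200) bounds the loop, and exhausting
it returns a fit flagged `converged = FALSE` rather than an error. If
every block is pruned the fit aborts with advice to lower $\tau$.

Initialization is $\gamma_b = 1$, $B = I$ per region and
$\sigma^2 = 0.1 \,\mathrm{Var}(y)$ -- a scale-free standard start; the EM
itself is deterministic, so fits are bitwise reproducible.

EM on a model whose support changes by pruning has no monotonicity
guarantee for the marginal likelihood; the per-iteration `log_evidence` in
the trace is a diagnostic only and is never asserted monotone.

### Centering

The regression has no intercept. Speller labels are heavily imbalanced
(2 targets in 12 stimuli), so $y$ has mean $-2/3$, which zero-mean
features cannot fit; the offset would sit in the residual forever,
inflate $\sigma^2$, and let noise channels chance-fit it. `fit_config()`
therefore centers the feature columns and labels by default
(`center = TRUE`), which is exactly equivalent to adding an intercept. Set
`center = FALSE` to run the literal intercept-free model -- the
transcription tests do, and the $\tau$-sensitivity sweep in the
acceptance checks uses it as well because the relevance floor of the
uncentered model is what makes "no pruning below $\tau = 10^{-6}$"
observable at unit data scale.

### The update order within one iteration

The three hyperparameter updates are computed from one shared posterior:
$\sigma^2$ from the previous prior and noise level, $\gamma$ from the
previous $B$, and $B$ from the same-iteration $\gamma$ (its update
formula divides by $\gamma_b$, and using the fresh value is the natural
EM reading). This ordering is a documented package decision; the
single-step transcription test pins it down exactly.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `tau` | `1e-4` | shear threshold on $\gamma$; also the final selection cutoff |
| `b_mode` | `"regional"` | correlation structure: `identity`, `shared`, `per_block`, `regional` |
| `max_prune_per_iter` | 5 | channels removed per iteration at most |
| `ar_clamp` | 0.98 | bound on the AR(1) coefficient of the constrained $B$ |
| `tol`, `max_iter` | `1e-4`, 200 | convergence control |
| `center` | `TRUE` | absorb the class-imbalance offset |

$\tau$ is the one parameter worth tuning per dataset
(`crossvalidate_tau()` does, by stratified k-fold AUC with ties resolved
toward the larger $\tau$, i.e. fewer channels). The $\gamma$ scale -- and
with it the right $\tau$ -- follows the squared scale of the fitted
weights, so it is problem-dependent: about $10^{-4}$ to $10^{-3}$ on
unit-variance EEG features regressed on $\pm 1$ labels, about 1 on the
unit-$\gamma$ block-sparse benchmark. A useful rule of thumb, used
throughout the package's own experiments: take $\tau$ around 10% of the
$\gamma$ scale expected for genuinely relevant channels, and
cross-validate inside $[10^{-6}, 10^{-1}]$ on unit-scale data. The
`b_mode` ablations exist because they isolate what temporal correlation
(`identity` vs the rest) and spatial sharing (`per_block` vs `regional`)
each contribute.

Note that the cross-validation folds stratify by stimulus label, not by
character trial: epochs of one character can land in different folds, so
validation scores are mildly optimistic on session data. This mirrors the
simplest defensible reading of a fold construction that the method
description leaves open, and is stated here so users with stricter needs
can fold by trial themselves.

## Regions and montages

Built-in montages `cap64` and `cap59` carry idealized 2-D coordinates
computed from the 10-10 label structure -- sufficient for region
building and topographic displays, not for source analysis. Their
13-region schemes follow standard 10-20 neighbourhoods with every region
at least 3 channels; exact memberships are an approximation and are
user-replaceable through plain-text region files (one region per line,
comma-separated channel names). Regions must strictly partition the
montage; overlapping or incomplete files are rejected with the offending
channels named. `auto_region_map()` clusters arbitrary montages
deterministically and merges undersized clusters into their nearest
neighbour.

## The classifier

`blda_fit()` is Bayesian linear discriminant analysis in its standard
P300 form: Bayesian linear regression on class-balanced targets
($+N/N_1$, $-N/N_2$), with the prior precision $\alpha$ and noise
precision $\beta$ estimated by evidence maximization (MacKay fixed
point), isotropic by default and per-feature (`prior = "ard"`) on
request -- the referenced literature does not say which the original
experiments used, so the conventional isotropic form is the default. At
convergence the weights coincide with ridge regression at
$\lambda = \alpha/\beta$, which is how the tests pin the implementation
down. Features and targets are centered internally and the bias is
recovered, so scores are proper affine functions of the input.

## The synthetic generators

`gen_block_sparse()` draws instances exactly from the model the prior
assumes (active blocks $\sim \mathcal N(0, \gamma\,\mathrm{Toeplitz}(r))$,
Gaussian design, additive noise at a requested SNR) and returns the
planted support -- the sharpest possible recovery oracle. Defaults are
the package's benchmark conditions: 40 blocks of 8 points, 8 active,
$r = 0.8$, 10 dB, 500 samples.

`gen_p300_session()` emulates a row/column speller session: every epoch
flashes the 12 codes once in random order, the two codes containing the
attended character are targets, and target rows add a Gaussian-in-time
bump (center 300 ms, sd 60 ms) to a planted set of 8 parieto-occipital
channels with spatially smooth amplitudes, on top of AR(1) channel noise.
Two features make the planted support identifiable rather than merely
present: a posterior-to-anterior latency gradient (0.3 s per montage
y-unit, mimicking the earlier visual components over occipital sites)
gives each informative channel a partly channel-specific time course, and
the default session length (36 characters, 4 epochs, 1728 stimuli
against 1770 features) keeps chance correlations of noise channels below
the planted effect. Optional distractor channels carry inflated noise for
selection-benefit experiments. Amplitude (1.5 vs noise sd 1.0) sits at
the optimistic end of single-trial ERP strength; it was chosen once,
together with the gradient, so that automatic selection recovers the
planted support with median F1 above 0.9 across seeds, and then frozen.

What the generator does *not* emulate: spatially correlated background
EEG, eye/muscle artifacts, trial-to-trial amplitude and latency jitter,
multi-component ERP shapes (a multi-bump option would be a small
extension), or non-stationarity across a session. Passing recovery tests
on these simulations therefore demonstrates correctness of the machinery
under the model's own assumptions, not performance on real recordings --
real-data validation needs real sessions, which the package reads through
`preprocess()` and the epoch container but does not ship.

## Numerical choices and degenerate inputs

* $\sigma^2$ is floored at `1e-10`: the update collapses at a perfect
  fit on separable toy data.
* Empty selections (`select_auto()` with $\tau$ above every $\gamma$) and
  fully pruned fits raise errors that say which direction to move $\tau$.
* `tau_sweep()` records a fully pruned fit as 0 selected channels instead
  of erroring, so threshold sweeps always complete.
* Fixed-M selection ranks by the importance score (the per-channel sum of
  absolute posterior-mean weights; $\gamma$ decides survival, the weights
  decide ranking) and, when the automatic selection kept fewer than `M`,
  backfills with the most recently pruned channels in reverse pruning
  order. The block-sparse model is not refitted after backfill; only the
  downstream classifier is retrained.
* Ties: pruning prefers the smaller $\gamma$ then the lower channel
  index; rankings prefer the lower channel index; row/column decoding
  prefers the lower stimulus code; $\tau$ cross-validation prefers the
  larger $\tau$. All stated so runs are exactly reproducible.
* `baseline_auto_threshold()` keeps scores exactly at the
  mean-minus-half-SD threshold, so constant importance vectors select
  every channel rather than none.
* Epoch extraction uses half-open `[onset, onset + window)` windows with
  0-based sample arithmetic at the decimated rate; the band edge must stay
  below the post-decimation Nyquist or `preprocess()` refuses to run.

## Problem sizes in the test and acceptance runs

The shipped checks run on: 100 random posterior instances up to
$40 \times 60$; the block-sparse benchmark at its default size (10
seeds); speller sessions of 36 characters (recovery, end-to-end benefit
with 16 distractor channels at 8x noise, decoding from 1 epoch) and 18
characters ($\tau$ sweep over $10^{-6} \dots 10^{-1}$); and a small
6-character experiment for bitwise determinism. These sizes were chosen
to exercise both posterior routes (N on either side of D) while keeping
a full run in the minutes range on a single core.

## Known limitations

* EM with hard pruning is greedy: a channel pruned early on cannot
  return, and the evidence is not guaranteed to increase across prunes.
* Regional smoothing helps exactly when neighbouring channels share
  temporal structure; with regions that mix signal and noise channels the
  shared $B$ is a compromise, and very unbalanced region sizes can tilt
  relevance estimates between regions.
* The AR(1) Toeplitz constraint is a deliberate rank-1 summary of the
  within-block correlation; richer structures (damped oscillations,
  multi-lag AR) are outside scope.
* Woodbury iterations cost $O(N^2 D)$; sessions with both $N$ and $D$ in
  the several-thousands are slow in plain R, which is one reason pruning
  caps matter in practice.
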