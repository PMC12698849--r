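---
title: "Split federated learning, label inference, and additive-noise defenses: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split federated learning, label inference, and additive-noise defenses: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, the threat model, the parameter choices,
and the numerical decisions behind `splitfedlab`. Everything here is the
package's own account of what it computes; the quantities quoted are the ones
the test suite and `scripts/acceptance.R` recompute at run time.

## The training protocol

Split federated learning (SplitFed) divides a classifier into a client part
$f_{c}$ (the input-side layers, parameters $\Phi_c$) and a server part $f_{s}$
(the remaining layers through the class scores). Each of $k$ clients holds a
disjoint shard of the training data with $n_i$ samples. For a minibatch $x$
with labels $y$:

1. the client computes the *smashed data* $h = f_c(x)$ at the cut layer and
   transmits it (with the labels, in the default wiring) to the main server;
2. the server computes scores $f_s(h)$, the mean cross-entropy loss
   $L(f_s(h), y)$, backpropagates, and updates $\Phi_s$ with the configured
   optimizer;
3. the gradient $\partial L / \partial h$ is returned to the client, which
   completes the backward pass and updates $\Phi_c$;
4. at the end of each round a federated server averages the client parts with
   weights $n_i / \sum_j n_j$ and redistributes the result, so all clients
   hold identical client-side parameters.

With $k = 1$ and no noise this is algebraically identical to centralized
training of the composed network; the test suite asserts trajectory agreement
to $10^{-5}$ after an epoch, and forward/backward agreement of the split and
monolithic compositions to $10^{-6}$ (gradients are additionally checked
against central finite differences at relative error $10^{-4}$).

The default architecture is
Conv(8, 3×3) → ReLU → MaxPool(2) → Conv(16, 3×3) → ReLU → MaxPool(2) →
**cut** → Flatten → Dense(64) → ReLU → Dense(C). Convolutions are valid
(no padding), stride 1. The cut sits after the second pooling layer so the
smashed data is a spatial activation map, and the score-producing head
(Flatten→Dense→ReLU→Dense) lives on the other side of the cut. The stack,
including the cut position, is fully configurable through
`split_model_spec()`. The loss is mean cross-entropy — the natural choice for
multi-class classification, and the one that makes candidate-label
enumeration in the attack well defined. The reference optimizer is Adam with
AMSGrad, learning rate 0.001, batch 64; plain SGD is provided because the
update equations of the protocol (and the noisy update rule below) are
written as plain gradient steps, and the corresponding tests run in SGD mode.

The engine computes convolutions by im2col and exact analytic backprop in
base matrix algebra. No GPU, no approximation: the attack below needs exact
per-sample parameter gradients, which is why the package owns this code path
rather than delegating to an opaque framework.

## The synthetic dataset

The generator emulates the structure of a four-class brain-MRI folder
(background / three lesion classes) without requiring any download: 32×32
grayscale images; class 0 is background noise only; class $c \ge 1$ carries
an elliptical lesion whose centre, radius and intensity are class-specific
(small/bright near the top-left through large/dim near the bottom-right),
with per-image jitter and additive pixel noise. Raw intensities live in
[0, 255]; preprocessing resizes and applies per-image min–max normalization
to $[-1, 1]$ (a constant image maps to all zeros, the range midpoint;
normalization is per-image so no global pass over the data is needed).

Defaults — 200 images per class, 20% held out, IID near-equal partition
across clients — are the study conditions for the acceptance runs. The
classes are deliberately separable: a small CNN exceeds 0.90 held-out
accuracy within a few epochs, which is what the real-data experiment this
emulates achieved at full scale (0.95 on 7023 brain-MRI images). What
passing these tests shows is that the *pipeline* — split training,
aggregation, attack, defense — behaves correctly on a classification task it
can solve; it says nothing about performance on real MRI data, with its
class imbalance, acquisition artifacts, and non-IID site effects.

## The label inference attack

The threat model is an honest-but-curious party that observes, for single
samples, (i) the cut activation $a = f_1(x)$ entering the attacked part and
(ii) the gradient of the loss at the true label with respect to the attacked
part's parameters, $g_y = \partial L(f_2(a), y) / \partial \Phi_2$. The
adversary holds a clone $\tilde f_2$ of the attacked part and enumerates every
candidate label $\tilde z$:

$$\tilde z^* = \arg\min_{\tilde z \in \mathbb{Y}}
  \operatorname{MSE}\!\left(g_y,\;
  \partial L(\tilde f_2(a), \tilde z) / \partial \tilde\Phi_2\right),$$

with exact ties broken toward the lowest label index. The MSE is taken over
the flat concatenation of all parameter gradients of the attacked part, and
the observation granularity is one sample (batched gradients would sum over
labels and change the problem).

Which part is "attacked"? The enumeration is only computable by an adversary
who knows the *input* of the part whose gradients it matches. The package
therefore attacks the score-producing part downstream of the cut: its input
is the smashed activation the adversary sees, and its parameter gradients are
the observed quantity. In the trained model this is the server-side head;
during label inference the party roles flip relative to training (the label
holder computes the loss), which is why the literature sometimes calls this
part the "client" in the attack setting. `run_attack()` supports an exact
clone (the default, the strongest adversary) and a re-initialised clone (the
degraded-knowledge variant).

Soundness: with an exact clone and noiseless observation, the MSE at the true
label is *exactly* zero and strictly positive at any label whose gradient
differs, so the attack recovers every label. This is the mechanism behind the
reproduced headline result — attack accuracy 1.0 without DP — and it holds
regardless of how well the model has converged.

## The additive-noise defense

`noise_spec()` describes a noise family (Gaussian, Laplace, Cauchy,
exponential) with location $\gamma$ and scale $\sigma > 0$, plus injection
targets:

- **parameters** — noise on outbound parameter copies
  (`param_noisy = param + noise`);
- **activations** / **gradients** — noise on the two transmission directions
  across the cut (`transmission_noisy = transmission + noise`);
- **update** — additive noise in the update rule,
  $\theta^{(t+1)} = \theta^{(t)} - \eta \nabla L + \text{noise}$.

Conventions that are dialect-prone and therefore fixed here: the exponential
family draws $\gamma + \operatorname{Exp}(\text{mean} = \sigma)$, i.e. it is
one-sided above its location with mean offset $\sigma$; the Laplace scale is
the diversity $b$; the Cauchy pdf is
$1/\!\left(\pi\sigma\left[1 + ((x-\gamma)/\sigma)^2\right]\right)$, so its
density at $x = \gamma$ is $1/(\pi\sigma)$. Samplers are checked against the
analytic CDFs by Kolmogorov–Smirnov tests at $\alpha = 0.01$, $n = 10^4$.

**Restoration.** Parameter noise perturbs only the copies shared for
aggregation; each client's clean local parameters are kept and reinstated
after the iteration (`restore_parameters()`), so noise never accumulates in
the state that keeps learning. Operationally: with targets = {parameters}
only, the training trajectory equals the noise-free trajectory exactly, while
every adversary-visible parameter copy is noisy. The alternative reading —
resetting to the *initial* parameters every iteration — would nullify
training and was rejected.

**Which channel defends against the attack.** With an exact clone,
activation noise cannot degrade the attack at all: the observed gradient and
every candidate clone gradient are computed at the *same* (noisy) activation,
so the true label still attains MSE exactly zero. The operative channel is
the returned gradient, and the degradation experiments therefore inject noise
there. Default sweep scales are $\sigma \in \{0.01, 0.1, 1, 10\}$ (the
source mechanism states none). No $(\varepsilon, \delta)$ accounting is
performed or claimed — there is no sensitivity analysis or clipping; the
defense's strength is assessed empirically through the attack.

**What the sweeps show.** Cauchy gradient noise degrades the attack
monotonically with scale, down to roughly the 0.25 chance level of the
four-class problem at $\sigma = 10$ (median over five seeds, 100 attacked
samples per run). At matched moderate scales the one-sided exponential noise
is the weakest defense, as its bounded, biased perturbations leave the argmin
largely intact ($\sigma = 1$: exponential median attack accuracy ≈ 0.55
versus ≈ 0.33 for Cauchy). At very large scales, however, the exponential
mean offset — which grows linearly in $\sigma$ — dominates the MSE
comparison and *systematically* steers the argmin to a wrong candidate,
pushing attack accuracy below chance (≈ 0.08 at $\sigma = 10$). Below-chance
attack accuracy under heavy noise is thus a real behavior of the noisy
argmin, not a defect: a plain-MSE adversary is biased, not merely blinded, by
one-sided noise. The corresponding acceptance expectation (Cauchy ≤
exponential at every matched scale) fails at the largest scale for exactly
this reason, and is left failing rather than weakened; the family ordering
holds at every scale where the attack remains above chance.

`run_noise_sweep()` supports two regimes: `retrain = TRUE` trains a model per
(family, scale, seed) with noise active during training — the full defense,
including its utility cost — while `retrain = FALSE` trains once per seed and
applies noise only to what the adversary observes at attack time, isolating
the privacy effect at a fraction of the cost. The acceptance sweeps use the
second regime with five seeds; the first is exercised at small scale in the
unit tests.

## Numerical and design notes

- Determinism: every stochastic step (initialisation, shuffling, partitioning,
  subset choice, noise) is derived from explicit integer seeds; repeated runs
  are bitwise identical. Seeded helpers restore the ambient RNG state.
- Parameter flattening order is stable and documented: layers in order,
  weights before biases. `part_flatten()`/`part_unflatten()` round-trip
  exactly; checkpoints store flat vectors at 17 significant digits, which
  round-trips IEEE doubles exactly.
- Max-pooling uses floor division; a trailing row/column that does not fill a
  window is dropped. Pooling ties resolve to the first element in column
  order, matching the backward routing.
- Degenerate cases: constant images normalize to all zeros; precision/recall
  for a class with no predicted/true positives is 0; `fedavg` rejects
  all-zero weights; a gradient packet applied to a different batch than the
  one it was computed for raises a "stale packet" error.
- Problem sizes (chosen as desk-scale study conditions): 800 synthetic
  images, 2 clients, early stop at 0.90 held-out accuracy within 15 epochs;
  100 attacked samples per run; degradation sweeps over 2 families × 4
  scales × 5 seeds.

## Known limitations

- The simulator is in-process: no real networking, encryption, asynchrony,
  or client dropout.
- Labels accompany the smashed data to the loss-computing party; the package
  records (and can flip) the wiring, but in a single-process simulation the
  arithmetic is identical either way.
- The attack assumes the adversary knows the attacked part's architecture; the
  exact-clone mode additionally assumes its current weights.
- No formal differential-privacy guarantees: the noise mechanisms have no
  calibrated privacy budget.
- The synthetic generator produces linearly well-separated classes; absolute
  accuracies on it are optimistic relative to real medical imaging.
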