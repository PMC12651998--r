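---
title: "Generating gene regulatory networks by discrete edge diffusion"
author: "DiffGRN authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating gene regulatory networks by discrete edge diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A gene regulatory network (GRN) is a directed graph in which a transcription
factor (TF) points at the genes whose transcription it controls. Recovering
such networks from single-cell RNA-seq expression is a classic inverse
problem: regulatory links are sparse, nonlinear and condition-dependent,
while most inference tools score each candidate edge independently and
therefore cannot enforce any global consistency on the result.

DiffGRN treats the network itself as the object being generated. A
parameter-free *forward* process progressively corrupts a clean network
toward a sparsity-encoding random graph; a learned *reverse* process —
conditioned on the expression profile of the sample — walks back along that
corruption, and in doing so proposes the whole network jointly rather than
edge by edge.

## The discrete diffusion model

Each ordered candidate pair (TF source, distinct target) carries a binary
state: edge or no edge. One corruption step applies the 2x2 row-stochastic
transition

$$M_t = \alpha_t S + (1 - \alpha_t) I,$$

where both rows of $S$ equal $(\delta, 1-\delta)$ and $\delta$ is the
stationary probability of *no* edge. Because $S$ is idempotent, $t$ steps
compose in closed form,

$$\bar M_t = (1-\bar\gamma_t) I + \bar\gamma_t S, \qquad
  1-\bar\gamma_t = \prod_{i \le t}(1-\alpha_i),$$

so a corrupted network at any time is one categorical draw away from the
clean one (`forwardSample()`). At $t = T$ the state is an independent
Bernoulli$(1-\delta)$ graph — all memory of the clean network is gone, which
the test suite verifies as a total-variation bound between forward marginals
started from complementary networks.

The per-step weights follow a squared-cosine retention profile
(`cosineSchedule()`), the standard choice when nothing is known about the
optimal corruption speed for the data at hand; the terminal retention is
floored at $10^{-5}$ so the stationary limit is reached exactly rather than
asymptotically.

$\delta$ is estimated from data (`estimateDelta()`): one minus the mean edge
density of the training networks over the candidate-pair universe, clamped
to $[0.5, 0.999]$. The clamp keeps the prior on the sparse side even for
unusually dense training collections, and bounds it away from degeneracy.

### Reverse process and accelerated sampling

Generation starts from the stationary graph and repeatedly applies the exact
two-state Bayes posterior

$$q(e_{t'} = k \mid e_t = j, e_0 = i) \propto
  M_{t' \to t}(k, j)\, \bar M_{t'}(i, k),$$

marginalized over the denoiser's predicted distribution of the clean state
$e_0$ (`edgePosterior()`). The bridge kernel $M_{t' \to t}$ has the same
closed form as $\bar M_t$, so the posterior is *exact for any pair of times*,
not just adjacent ones. Accelerated sampling therefore needs no
approximation: `makeSubsequence(T, k)` picks an evenly spaced ladder of
$k \le T$ times, and the same trained model runs on the shorter ladder. At
$k = T$ this reduces to ordinary ancestral sampling, which the tests check
by comparing single-step Monte-Carlo marginals. The sampler is stochastic
by default; a `deterministic` flag switches each step to the posterior mode
for users who want repeatable hard jumps.

Two design points here were genuinely open:

* **Skip-step semantics.** "Accelerated" sampling is implemented as the
  exact discrete bridge posterior over the subsequence, not a continuous-time
  ODE analogue: correctness at $k = T$ is then automatic and every shorter
  ladder stays a valid Markov chain.
* **Ensemble readout.** The returned edge probability is the mean, across
  independent reverse chains, of the predicted clean-edge probability at the
  final step (`generateNetwork()`). Averaging predicted probabilities rather
  than sampled binary networks gives a lower-variance estimate at the same
  cost; sampled networks remain available through `thresholdNetwork()`.

## The denoiser

`denoiserForward()` implements a hybrid-attention graph transformer that maps
(noisy network, expression, time) to per-pair clean-edge logits.

**Node initialization.** Each gene enters as its standardized expression
profile across `mProfile` (meta)cells concatenated with six marginal
statistics (mean, sd, dropout fraction, quantiles), linearly projected.
The profile — not just its summaries — is essential: the pairwise edge
scores downstream are bilinear forms $Q_i K_j^\top$ in the node features, and
only features that share the cell axis let such a form express
correlation-like evidence between a TF and its target. Marginal summaries
alone would make distinct targets with similar distributions
indistinguishable, collapsing edge identification to chance. For the same
reason `mProfile` should not exceed the node width `dX`: the bilinear score
has rank at most `dX`, so profiles longer than `dX` are aggregated into
metacells first (`metacellAggregate()`), which also suppresses dropout
noise.

**Time-gated GATv2 encoder.** Two multi-head GATv2 layers (heads
concatenated, then averaged) aggregate each gene's neighborhood in the
*current noisy network*; a sigmoid gate driven by the sinusoidal time
embedding interpolates between the aggregated features and the original
projection. At high noise the gate can shut out the (mostly random)
neighborhood and keep the expression signal; at low noise it can lean on the
nearly clean structure. Isolated nodes fall back to self-attention only.

**Graph transformer layers.** Each of the `L` layers updates three streams:

* *Nodes*: standard scaled dot-product self-attention across genes, fused
  with time through FiLM ($\mathrm{FiLM}(a,b) = \mathrm{lin}_1 a +
  \mathrm{lin}_2 a \cdot b + b$), then residual + layer norm + a small
  feed-forward block.
* *Edges*: per-head bilinear pair scores from the node stream form an edge
  proposal $E_{self}$; the fed-back noisy-network embedding, FiLM-fused with
  time, is read through cross-attention. Each ordered pair attends over a
  two-token memory — its own feedback state and that of the *reverse* pair —
  which keeps the cost at $O(n^2)$ while letting the model exploit the
  strict unidirectionality of the edge universe (observing $j \to i$ is
  evidence against $i \to j$). An all-pairs cross-attention would cost
  $O(n^4)$ and is out of scope.
* *Time*: the embedding is advanced by a linear map plus two learned
  poolings — a sigmoid-gated sum over node features and a learned-query
  attention over candidate-pair edge features. The update runs between
  layers; after the last layer the embedding has no consumer, so the final
  update is omitted rather than trained with dead parameters.

Masked pairs (non-TF source or diagonal) are forced to the "absent"
embedding on input and to a $-10^9$ edge logit on output, keeping every
array rectangular while making their probability exactly zero after the
softmax. The whole pass is equivariant to gene permutations — verified in
the tests by permuting expression and network jointly — and deterministic
given parameters and inputs.

Ablation switches reproduce the architecture variants studied in the
benchmarks: `ablateG` replaces the GATv2 encoder with a linear projection,
`ablateC` passes $E_{self}$ through untouched, `ablateP` swaps both
poolings for plain means.

## Training

`trainModel()` draws, per step, a training network and a uniform
$t \in \{1..T\}$, corrupts the clean network with the closed-form forward
marginal, and descends the masked cross-entropy between the predicted and
the clean network with AdamW (decoupled weight decay, global-norm clipping).
Sparsity makes the positive class rare, so true-edge pairs receive the
weight (#candidates − #edges)/#edges computed on the training set, capped
at 20; with uniform logits the loss is exactly $\log 2$ regardless of the
weighting, which the tests pin down.

**Cell-bootstrap augmentation.** With desk-scale collections of a few dozen
networks, the denoiser is expressive enough to memorize each training
network from its expression signature, which generalizes badly. Each
network therefore contributes `augmentCells` feature variants derived from
random 80% subsamples of its cells; steps cycle through them. Pairwise
dependence survives resampling while incidental per-network signatures do
not, so the augmentation steers optimization toward the transferable
evidence. This, plus weight decay, is the package's main defense against
memorization; it is on by default.

**Scheduled sampling.** A reverse chain feeds the denoiser networks of its
own making, while plain training only ever shows it corruptions of the
truth — a mismatch that compounds errors along the chain (early wrong edges
get copied forward at low noise). A fraction of training draws
(`selfCorruptProb`, default 0.3) therefore corrupts a network *sampled from
the model's current prediction* instead of the true one, while the loss
target remains the true network. This exposes the model to its own feedback
distribution and measurably reduces the gap between one-shot prediction and
chain output.

Divergence (a non-finite loss) aborts with a diagnostic rather than
continuing silently. Checkpoints are single RDS files whose round trip is
bit-exact; `writeModelHeader()` exposes the hyperparameters, feature recipe
and schedule fingerprint as JSON. A model refuses to generate under a
schedule that contradicts its stored fingerprint.

## The benchmark simulator

`makeBenchmarkSuite()` provides the controlled environment for training and
evaluation: random sparse topologies and matched steady-state expression.

Topologies draw the gene count uniformly (default 15–40 at desk scale),
designate a TF fraction (default 0.3), and place a uniformly drawn number of
edges between $n$ and $2n$ under three constraints — no self-regulation,
TF-only sources, and no reciprocal pairs (the strictest reading of
unidirectional regulation; TF→TF edges are allowed in one direction).
Infeasible configurations fail loudly.

Expression integrates a simplified chemical-Langevin system per cell:
production $b_j + \sum_i k_{ij}\,\mathrm{Hill}(x_i)$ against linear decay
$\lambda_j x_j$, with demographic noise
$\eta\sqrt{(p_j + \lambda_j x_j)\,dt}$ and independent cells as independent
realizations. Activating edges (probability 0.7) use the increasing Hill
function, repressing edges the decreasing one; Hill coefficient 2 with
half-saturation on the basal scale. Kinetics are drawn for *every* ordered
pair and masked by the adjacency, so an edge knockout leaves the random
stream of unrelated genes untouched — the test suite exploits this for a
paired knockout check (removing an edge shifts the target's distribution by
a KS test and leaves bystanders bit-identical). Defaults — basal
$U(0.5,1.5)$, $|k| \sim U(2,6)$, decay $U(0.8,1.2)$, unit noise scale,
$dt = 0.05$, 200 burn-in steps, 100 cells per network — were fixed once as
a realistic operating point for steady-state single-cell simulators.

What the simulator does *not* emulate: differentiation trajectories,
technical count noise and dropout modules, batch effects, or genome-scale
gene panels. Passing benchmarks here shows that the method recovers sparse
nonlinear TF→target structure from steady-state profiles — not that it
would survive every artifact of real scRNA-seq data.

## Evaluation

`scoreNetwork()` ranks the candidate universe with mid-rank tie handling
(AUROC), tie-grouped average precision (AUPRC), and F1 at a declared cutoff
(default 0.5, with the best-F1 along the PR curve reported separately and
labeled as such — no cutoff rule is implied by the ranking metrics). The
baselines are the field's minimal references: absolute Pearson correlation
and equal-frequency 8-bin histogram mutual information per candidate pair,
min–max scaled. `runBenchmark()` and `runAblation()` wrap these into
deterministic, seed-stamped reports; ablations retrain from scratch per
variant under identical data and seeds so differences are architectural
only.

`regulatorySummary()` condenses generated networks for downstream biology:
per-TF regulatory intensity is the *sum of outgoing edge probabilities*
(out-degree at a cutoff is reported alongside; an expression-weighted
variant would also be defensible, but probabilities are the model's native
output), hub TFs are the top-$k$ by intensity, and cross-condition activity
is the per-gene variance of intensity.

## Numerical choices and problem sizes

* Posterior normalizers falling to zero (possible only for degenerate
  schedules) are floored at $10^{-12}$ and logged.
* Softmax rows subtract their row maximum before exponentiation; the
  $-10^9$ logit mask plays the role of $-\infty$ without producing NaNs.
* All randomness flows from one integer seed through counter-based
  substreams, so suites, training runs and ensembles are reproducible
  element-wise; seeded functions restore the caller's RNG state.
* Default architecture: `L = 3` transformer layers, 4 heads, `dX = 64`,
  `dE = 32`, `dT = 64`, LeakyReLU slope 0.2. The packaged experiments and
  tests run a desk-scale variant (`L = 2`, 2 heads, `dX = 32`, `dE = 16`,
  `dT = 32`, `mProfile = 32`) with `T = 100` diffusion steps, a few dozen
  simulated networks of 15–30 genes and 100 cells, chosen so the full
  train-generate-evaluate cycle completes in minutes on one CPU core; the
  same code paths scale to the full-size setting unchanged.
* The denoiser and its training run on a small reverse-mode tape engine
  written for this package; every primitive's vector-Jacobian product is
  tested against central finite differences, and the full loss gradient is
  spot-checked the same way.

## Known limitations

* Desk-scale accuracy is information-limited: with 100 noisy cells per
  network, even a supervised classifier over pairwise dependence features
  plateaus well below perfect ranking, and the trained denoiser operates
  near that ceiling. The benefit of the structural feedback machinery
  (graph attention over the noisy network, cross-attended feedback) grows
  with the size of the training collection; with only a few dozen
  networks, a feedback-blind ablation can match or exceed the full
  architecture, and reverse chains add sampling noise without adding
  information. The packaged ablation harness makes this comparison
  directly.
* Edge states are binary; signed or weighted regulation is not modeled.
* The cross-attention memory is pairwise-aligned (pair and reverse pair),
  a deliberate $O(n^2)$ restriction of full pair-to-pair attention.
* Dense matrices throughout: intended for focused panels (up to a few
  hundred genes), not genome-wide inference.
* Real-data reference networks, multi-omics conditioning and comparisons
  against external inference tools are out of scope; the correlation and
  mutual-information baselines are reimplemented here, everything else is
  not.
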