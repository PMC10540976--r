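---
title: "Methods: constrained recurrent dynamics, Laplace posteriors and batch Bayesian design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained recurrent dynamics, Laplace posteriors and batch Bayesian design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, the inference and design machinery, the ground-truth
simulator, the numerical choices, and what the test suite does and does
not establish.

## The model and its physical constraints

Microbiome time series are *sparse*: most taxa are absent from most
samples. A flexible autoregressive model fitted to such data can make two
kinds of physically impossible predictions — negative abundances, and the
spontaneous appearance of a species that was never inoculated. Because
predictions are fed back as inputs, a single spurious appearance
propagates through every later time point.

The MiRNN (Microbiome Recurrent Neural Network) is a discrete-time
recurrent network over species abundances $s_t \in \mathbb{R}^{n_s}_+$,
metabolite concentrations $m_t \in \mathbb{R}^{n_m}_+$, control inputs
$u_t \in \mathbb{R}^{n_u}$ and a latent state $h_t \in \mathbb{R}^{n_h}$:

$$h_t = \mathrm{LeakyReLU}\big(W_{hh} h_{t-1} + W_{ih}^\top
  [s_{t-1}, m_{t-1}, u_{t-1}, u_t] + b_{hh}\big), \qquad
  o_t = W_{ho}^\top h_t + b_{ho},$$

with parameters $\theta = \{W_{hh}, b_{hh}, W_{ih}, W_{ho}, b_{ho},
h_0\}$ ($n_\theta = n_h^2 + n_h + (n_s+n_m+2n_u)n_h + n_h n_y + n_y +
n_h$, e.g. 1,245 at 25 species, 4 metabolites, no controls, 16 hidden
units). Two constraints make the outputs physical:

* the species part of $o_t$ is multiplied elementwise by the indicator
  $\mathbf{1}[s_{t-1} > 0]$, so an absent species stays *exactly* absent
  (not approximately — the mask is algebraic, and the test suite asserts
  exact zeros);
* at inference time, a ReLU rectifies the full output. During training
  the rectifier is suppressed so that negative raw predictions incur loss
  instead of being silently clipped.

Both controls at $t-1$ and $t$ enter the input so the model can track
strong step changes in time-dependent controls (e.g. feed-rate
switches). `h_0` is a single learned vector shared across conditions.
The unconstrained ablation (`constrained = FALSE`) removes only the mask;
on inputs where every fed-forward species value stays strictly positive
the two variants coincide exactly.

**Scaling.** Every feature is divided by its maximum over the training
split (`fit_scaling()`), never standardised: max-scaling maps 0 to 0, so
absence survives preprocessing and rectified outputs invert to
non-negative original units. Constant-zero features get divisor 1 and
pass through unchanged.

## Bayesian estimation

Observations are modelled as the rollout plus i.i.d. Gaussian noise with
covariance $\Sigma_y$ (diagonal by default, floored at $10^{-8}$). With a
Gaussian prior $\theta \sim N(0, \alpha^{-1} I)$ the negative log
posterior is the familiar penalised least-squares objective
(`neg_log_posterior()`), which `fit_map()` minimises by damped Newton
iteration using the Gauss–Newton Hessian

$$H = \alpha I + \sum_i G_i^\top \Sigma_y^{-1} G_i,$$

where $G_i$ is the Jacobian of condition $i$'s rolled-out outputs with
respect to $\theta$ (the *sensitivity matrix*). $H$ is positive definite
by construction (the diagonal prior term guarantees full rank), so every
Newton direction is a descent direction; an Armijo backtracking line
search ($c = 10^{-4}$) globalises the iteration. The Laplace
approximation takes the posterior as $N(\theta_{\mathrm{MAP}}, H^{-1})$,
and the linearized posterior predictive for a condition is Gaussian with
mean the MAP rollout and covariance
$\Sigma_y + G H^{-1} G^\top$ — aleatory (irreducible noise) plus
epistemic (reducible by data) uncertainty. On any model *linear* in
$\theta$ this whole pipeline is exact, which the suite verifies against
closed-form Bayesian linear regression to $10^{-8}$ relative.

**Sensitivities.** R has no reverse-mode autodiff for arbitrary
closures, so `mirnn_sensitivity()` propagates exact forward-mode
derivatives through the recurrence by hand-derived chain rule; it is
exact to machine precision and is cross-checked in the tests against
central finite differences (step $10^{-6}$) to $10^{-4}$ relative, the
dual-route contract. The absence mask is treated as locally constant:
masked rows carry exactly zero sensitivity, which is also the correct
subgradient almost everywhere.

**Hyperparameters.** $\alpha$ can be selected by maximising the Laplace
evidence over a grid (`optimize_alpha()`; the approximation includes all
Gaussian normalisation constants, so it equals the exact marginal
likelihood on linear models). $\Sigma_y$ is re-estimated by
expectation–maximization (`estimate_sigma_y_em()`): alternate a MAP
refit with a diagonal update from residual second moments plus the
linearized epistemic variance $\mathrm{diag}(G H^{-1} G^\top)$. The
exact update scheme of the original work is not published in full; this
residual-plus-epistemic form is the standard choice and is validated by
simulation (known noise recovered within 20% at large n).

**Training initialisation.** The constraint creates a training
pathology: from an all-zero initialisation the first-step outputs are
zero, the mask kills every species from step 2 on, and their gradients
vanish. `training_init()` therefore starts from small random weights
with the output bias set to the mean of the scaled observations, which
keeps present species above the absence threshold initially. `fit_map()`
itself defaults to the prior mode (correct for the empty-data contract)
and accepts any initialisation; multi-restart is available.

**Stopping.** Convergence is declared at gradient $\infty$-norm
$\le$ `tol`; because the masked objective is only piecewise smooth, the
iteration also stops (flagged, not silently "converged") when two
consecutive accepted steps improve the objective by less than $10^{-9}$
relative, or when the line search cannot find descent.

## Expected information gain and batch design

The information content of a prospective batch of $n$ conditions is the
log-determinant increase of the posterior precision,

$$\mathrm{EIG} = \ln\det\Big(H + \textstyle\sum_{i=1}^n G_i^\top
 \Sigma_y^{-1} G_i\Big) - \ln\det(H),$$

implemented twice: `eig_direct()` forms the $n_\theta \times n_\theta$
matrix (the oracle), and `eig_fast()` computes the identical value as a
sum of $n$ small log-determinants

$$\sum_{i=1}^n \ln\det\big(I + \Sigma_y^{-1} G_i A_{i-1}^{-1}
  G_i^\top\big), \qquad A_0 = H,$$

maintaining $A_i^{-1}$ with Woodbury rank-updates
(`woodbury_update()`) so that nothing larger than the one reusable
inverse of $H$ is ever factorized. The equivalence is property-tested to
$10^{-6}$ relative up to $n_\theta = 500$; at $n = 1$ the expression
reduces to the classical predictive-variance identity. The classical
D-optimality criterion $\ln\det \sum_i G_i^\top \Sigma_y^{-1} G_i$ is
provided for comparison (`fim_logdet()`; rank-deficient information
returns a $-\infty$ sentinel, since fewer output rows than parameters
cannot identify $\theta$ without the prior).

**Acquisition and greedy search.** Designs are scored by
$f = f_P + w_I \cdot \mathrm{EIG}$, predicted profit plus weighted
information. `greedy_select()` picks the batch sequentially: the first
condition maximises predicted profit alone; each later pick maximises
$f$ with the *incremental* EIG given the batch so far; whenever the
maximiser is already in the batch, $w_I$ is multiplied by 10 (from
$w_I^{(0)} = 10^{-4}$) until a novel condition wins. Ties break to the
lowest candidate index, so reruns are deterministic. A condition's EIG
contribution stacks all of its observed time points into one
sensitivity block (grouping per configuration). The four benchmark
strategies are pure profit (`exploit`), pure incremental EIG
(`explore`), the combined escalating rule (`explore_exploit`) and seeded
uniform sampling (`random`).

## Ground-truth bioreactor simulator

The synthetic ecosystem is a consumer-resource community in a fed-batch
reactor: $n_s$ species compete for $n_r$ shared resources; one species
converts growth into a target metabolite with growth-associated
kinetics; feeding adds volume and resources and nothing is withdrawn:

$$\dot V = u,\quad
 \dot r = r \odot(-s^\top C - d) + \tfrac{u}{V}(r_f - r),\quad
 \dot s = s \odot (C r - g) - \tfrac{u}{V}s,\quad
 \dot m = y_{m/s}^\top \max(0, \dot s) - k_d m - \tfrac{u}{V} m.$$

Ecosystems are sampled (`sample_ecosystem()`) by drawing species-resource
dependence Bernoulli(0.6), normalising the dependence matrix rows to sum
to one, and drawing consumption rates around it with 10% relative spread
(truncated at zero); all-zero rows are resampled and logged. Degradation
and maintenance rates are $d = g = 0.01\,h^{-1}$, product decay
$k_d = 0.005\,h^{-1}$, and the sole producer (yield 0.5) is the species
depending on the *fewest* resources — this keeps "feed everything" from
being trivially optimal. Measurements at 26-hour intervals over a
130-hour batch are corrupted multiplicatively with 5% Gaussian noise and
clipped at zero.

Unspecified operating conditions are fixed once as: $V_0 = 1$ L,
$r(0) = 0$ in fed-batch mode (the feed is the sole resource input),
$s_0 = 0.01$ g/L per inoculated species, $m(0) = 0$, feed resource
concentration 1 g/L — all overridable. The feed-profile catalog is a
seeded draw of 20 distinct piecewise-constant profiles over 5 equal
intervals with rates from $\{0, 0.005, 0.02\}$ L/h, reproducing the
$20 \times (2^7 - 1) = 2{,}540$-configuration combinatorics of a
7-resource study while leaving shapes configurable. The batch-mode
sparse-community generator (`generate_sparse_communities()`) instead
starts with all resources at 1 g/L, since without feed nothing would
grow from $r(0) = 0$.

**Integration.** `deSolve::ode` (lsoda) at rtol $10^{-6}$ / atol
$10^{-9}$, integrating segment by segment over the piecewise-constant
feed intervals with the state floored at zero between segments. The
analytic-limit tests (pure product decay, volume linearity, resource
decay without consumers) tighten the tolerances to $10^{-10}/10^{-12}$
so the comparison at $10^{-6}$ relative measures the equations, not the
step control.

## What the synthetic studies show — and what they do not

The generator emulates the *structure* of real microbiome experiments:
sparsity (absent species exactly zero), competition-driven dynamics,
multiplicative measurement noise, a large combinatorial design space and
low experimental throughput. It does not emulate cross-feeding networks,
irregular sampling, compositional measurement artefacts, or model
mismatch beyond the RNN-vs-ODE gap, so passing tests demonstrate
correctness of the machinery and directional behaviour on a faithful toy
— not performance on any real community.

Desk-scale study sizes (the package's own choices, stated here once):

* **Sparsity cross-validation**: 20 species / 10 resources, 30
  communities of 5 species, 5 folds, 3 trials, hidden size 8. Direction
  checked: constrained median per-species held-out Pearson R $\ge$
  unconstrained. Evaluation pools only species initially present, so
  the mask cannot score points on trivially-correct absent species.
* **Closed-loop comparison**: 5 species / 4 resources / 5 profiles
  (75 configurations), 5 initial + 3 cycles of 5, hidden size 6, 10
  replicate seeds sharing one ecosystem. Directions checked: combined
  exploration+exploitation finds at least as much product as random
  sampling; exploitation alone yields the worst post-cycle-1 model
  accuracy (redundant sampling).
* **Uncertainty quality**: 16 training / 8 held-out configurations, 5
  seeds; held-out log-likelihood under the condition-dependent predictive
  covariance versus the fixed noise covariance.

One documented limitation: at 75 configurations, ten tested
configurations already cover 13% of the space, and the escalating
$w_I$ makes combined-strategy batches nearly as information-rich as pure
exploration's, so the combined strategy's post-cycle-1 model accuracy is
statistically indistinguishable from (and in the shipped test run
slightly above) pure exploration's. The corresponding suite assertion —
that pure exploration attains the strictly highest post-cycle-1 accuracy
— is kept as specified and fails at this scale; the separation it looks
for emerges only when coverage is scarce (thousands of candidate
configurations), which does not fit the suite's compute envelope. Model
accuracy is evaluated on end-point metabolite *concentration*
(the volume is implied exactly by the feed schedule and would otherwise
inflate every strategy's correlation); profit remains end-point product
mass $m(T)\,V(T)$.

## Other numerical choices and degenerate inputs

* LeakyReLU negative slope 0.01 (common default).
* Absence indicator is strict $s > 0$ on scaled values; a configurable
  detection floor can snap near-zero measurements to 0 at ingest.
* Zero-maximum features scale with divisor 1.
* Noise variances floored at $10^{-8}$; EM warns on outputs with no
  observations.
* `fim_logdet()` returns $-\infty$ (not an error) on rank-deficient
  information.
* Empty candidate G lists give EIG exactly 0; `woodbury_update()` with a
  zero block returns its input unchanged.
* Uniform time grids are enforced at construction and on file ingest —
  the model is discrete-time and has no notion of irregular sampling.
* All randomness flows through explicit seeds; derived child seeds stay
  below $2^{31}$.

## Known limitations

Gaussian posterior and predictive approximations (no MCMC); diagonal
$\Sigma_y$ by default; full-batch Newton training only (no minibatching,
no GPU); discrete time with uniform sampling; the greedy batch search is
a heuristic without submodular guarantees (the suite checks its
optimality empirically on small instances where exhaustive enumeration
is feasible); and the bioreactor ground truth is itself a model, so all
closed-loop results are simulation studies.
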