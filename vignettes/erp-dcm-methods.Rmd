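---
title: "Methods: neural-mass ERP modelling, variational inversion and fabric-aware Jacobian scheduling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neural-mass ERP modelling, variational inversion and fabric-aware Jacobian scheduling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpdcm)
```

# The generative model

## Neuronal dynamics

Each cortical source is a Jansen-type neural mass with three populations —
spiny stellate cells (granular layer), pyramidal cells (infragranular) and
inhibitory interneurons (supragranular) — and nine states: for each of the
three synaptic ensembles, a membrane potential and its current obey
second-order kinetics

$$\ddot v = \frac{H}{\tau}\,m(t) - \frac{2}{\tau}\dot v - \frac{v}{\tau^2},$$

where $m(t)$ is the presynaptic input, $H$ the synaptic gain (in mV; `H_e`
for excitatory synapses, `H_i` for inhibitory ones) and $\tau$ the synaptic
time constant in ms (`tau_e`, `tau_i`). The impulse response of one synapse
is $H\,(t/\tau)\,e^{-t/\tau}$ scaled by $1/1000$: gains are expressed per
unit firing rate per second while time runs in milliseconds, so the static
gain of a synapse is $H\tau$ in mV·s — 0.032 mV·s for the default excitatory
values $H_e = 4$ mV, $\tau_e = 8$ ms. Potentials are converted to firing
rates by the centered sigmoid

$$S(v) = \frac{1}{1+e^{-r(v-\eta)}} - \frac{1}{1+e^{r\eta}},$$

with slope $r$ (1/mV) and threshold $\eta$ (mV); the centering makes rest
($x = 0$, no input) an exact fixed point. The four intrinsic couplings
$\gamma_1..\gamma_4$ close the loops: pyramidal firing excites the stellate
($\gamma_1$) and inhibitory ($\gamma_3$) populations, stellate firing drives
the pyramidal population ($\gamma_2$), and the interneurons inhibit it
($\gamma_4$). Defaults are the standard values $\gamma = 128\,(1, 0.8, 0.25,
0.25)$, $r = 0.56$, $\eta = 6$.

Sources are coupled by three kinds of extrinsic connections, encoded as
masked matrices whose entry $(i,j)$ couples source $j$'s pyramidal firing
into source $i$: forward connections terminate on the spiny stellate
population, backward and lateral connections on the pyramidal and inhibitory
populations. The population targets are configurable (`targets` in
`model_spec()`), so ascending/descending asymmetries other than the default
can be expressed. The stimulus — a Gaussian bump $u(t)$ parameterized by
onset, width and amplitude — enters the stellate population of the sources
named by the input mask.

Every free parameter is a log-scaling of a positive baseline: effective
couplings are `base * exp(theta)`, with baselines 32 (forward), 16
(backward), 4 (lateral) and 32 (input gain), so positivity is structural and
priors live on a common log scale. Condition-specific modulations multiply a
connection by a further `exp(theta_mod)` in every non-baseline condition
where that connection is flagged as modulated. The flat parameter vector
(enumerated by `parameter_map()` in a fixed order) and its structured matrix
view round-trip losslessly; its length $N$ is the model complexity that
drives the per-iteration workload.

The nine-state layout deliberately carries the pyramidal potential as a
separate state whose derivative is the difference of the two pyramidal
currents. This makes one linear combination per source conserved, so the
system Jacobian $J = \partial f/\partial x$ is structurally singular — a
fact the integrator (below) has to respect — and the spectrum at rest has
exactly one zero eigenvalue per source; all remaining eigenvalues have
strictly negative real parts under the default priors.

## Integration

Trajectories are computed by local linearization: over a step $\Delta t$,

$$x_{k+1} = x_k + \left(e^{\Delta t J_k} - I\right) J_k^{-}\, f(x_k, u_k),$$

with $J_k$ the analytic system Jacobian at the current state. Because $J_k$
is singular by construction, $J_k^{-}$ is a Moore–Penrose pseudo-inverse
(singular values below $10^{-10}$ of the largest are treated as zero); any
null-space component of $f$ advances linearly over the step. The compiled
(RcppArmadillo) engine evaluates the same update through the augmented
exponential $\exp\!\big(\Delta t \left[\begin{smallmatrix} J & f\\ 0 &
0\end{smallmatrix}\right]\big)$, whose top-right block is $\int_0^{\Delta t}
e^{sJ} f\,ds$ — identical to the pseudo-inverse form whenever $f$ lies in
the range of $J$, which it always does here because the conserved mode is
respected by the dynamics. The plain-R reference implementation of the
explicit formula is kept and the two engines are required to agree to
machine precision in the test suite.

The stimulus is held constant over each step at its midpoint value; this
makes the step error second-order in $\Delta t$ for a smooth input. At a
1 ms step the trajectory of the default two-source model stays within
$10^{-3}$ of the peak amplitude of an adaptive Runge–Kutta solution at
tolerance $10^{-10}$, which is the accuracy contract asserted in the tests.
Non-finite states abort with an error naming the offending time index.

## Observation

Sensor data are a linear mixture of the sources' pyramidal depolarizations:
$h = L\,x_9$ with a lead field $L$ (channels × sources). Lead fields are
supplied as matrices or TSV files, or sampled with seeded standard-normal
entries and unit column norms; head modelling is out of scope. The map from
source activity to channels is exactly linear, so channel permutations and
gain rescalings commute with prediction.

# Inversion

## Free energy

With observation precision $\Pi(\lambda) = \sum_i e^{\lambda_i} Q_i$
(diagonal components; a single identity component by default, or one per
channel) and Gaussian priors $\theta \sim N(\mu, \Sigma_\theta)$, the
variational-Laplace bound on log evidence is

$$F = -\tfrac12 e^\top\Pi e + \tfrac12\log|\Pi|
 - \tfrac12(\theta-\mu)^\top\Sigma_\theta^{-1}(\theta-\mu)
 + \tfrac12\log\frac{|\Sigma_{post}|}{|\Sigma_\theta|}
 - \tfrac{n}{2}\log 2\pi,$$

with $e = y - h(\theta)$ and $\Sigma_{post} = (J^\top\Pi J +
\Sigma_\theta^{-1})^{-1}$ at the current response Jacobian $J =
\partial h/\partial\theta$. Parameters with zero prior variance are frozen:
they are excluded from the prior and Occam terms and never move.

## EM loop

Each iteration recomputes the response Jacobian by one-sided finite
differences (step $10^{-4}$ on the log scale, configurable; halving the step
changes columns by under $10^{-3}$ in relative norm on the default models),
then:

* **E-step** — Gauss–Newton ascent
  $\Delta\theta = (J^\top\Pi J + \Sigma_\theta^{-1})^{-1}
  (J^\top\Pi e + \Sigma_\theta^{-1}(\mu-\theta))$, with step halving (up to
  8 times) until the free energy does not decrease. A numerically singular
  curvature gets a logged ridge of $10^{-8}\,\mathrm{tr}(P)/N$.
* **M-step** — Fisher-scoring ReML update of the log-precisions, whose
  gradient $\tfrac12[\mathrm{tr}(\Pi^{-1}P_i) -
  \mathrm{tr}(\Sigma_{post}J^\top P_i J) - e^\top P_i e]$ (with $P_i =
  e^{\lambda_i}Q_i$) accounts for posterior parameter uncertainty; single
  Fisher steps are damped to at most 4 and $\lambda$ is clipped to
  $[-32, 32]$. The hyperparameter move is halved until it does not decrease
  $F$.

Because the Jacobian is re-linearized every iteration, the Occam term can
bookkeep differently across iterations even when nothing moved; an
iteration-level guard therefore accepts a move only if it does not lower the
recorded free energy, reverting otherwise (Levenberg-style), so the reported
trace is non-decreasing by construction. EM starts deterministically at the
prior mean — no random restarts — and stops when the free-energy gain stays
below 0.01 nats on two consecutive iterations, or after 128 iterations.
On a linear forward map the first E-step lands exactly on the conjugate
Gaussian posterior and the final free energy equals the analytic log
marginal likelihood; both identities are asserted in the tests.

All arithmetic is double precision on a single code path: the serial and
pooled Jacobian backends execute the identical per-task arithmetic in the
identical within-task order, so inversions agree to $10^{-12}$ regardless of
strategy or worker count. That contract removes the cross-platform
divergence risk inherent in running the same model on heterogeneous
arithmetic stacks.

# The Jacobian engine and the execution fabric

The response Jacobian costs $N + 1$ full state integrations per EM iteration
— one shared base response plus one per perturbed parameter — and these
tasks are independent. `make_jacobian_tasks()` materializes them with ids
$0..N-1$; the pooled backend groups tasks into blocks with a scheduling
strategy and runs blocks on a fork pool, falling back to serial execution
with a warning if the pool fails.

The scheduler models a GPU-like fabric: `n_sm` streaming multiprocessors,
each hosting at most a capability-dependent number of resident blocks (8 for
capability classes 1.x/2.x, 16 for 3.x), blocks of capacity at most 1024
tasks executing in warps of 32. The concurrency limit is $X = n_{sm} \times
\text{resident limit}$ — 64 for the default 8-SM class-2.x fabric. Three
arrangements are implemented:

* **thread-first** — fill each block to capacity before opening the next
  ($\lceil n/1024\rceil$ blocks);
* **block-first** — one task per block ($n$ blocks);
* **blockX** — round-robin the tasks over exactly $X$ blocks, one task per
  block per pass, spilling to a fresh set of $X$ blocks once all are full.
  With fewer than $X$ tasks only nonempty blocks are emitted, and block
  sizes never differ by more than one. Round-robin places single tasks per
  pass (strided), not contiguous chunks.

The cost model is deliberately simple and deterministic: blocks run in waves
of at most $X$ in index order, a block costs $\lceil\text{size}/32\rceil$
units (warps serialize within a block), a wave costs its slowest block, and
the makespan is the sum of wave costs. It reproduces the characteristic
step pattern — cost jumps each time the block count crosses a multiple of
$X$ — which is also how `detect_concurrency_limit()` finds $X$: probe
single-warp blocks at increasing counts and return the count at which cost
first steps up. The simulated probe recovers the hidden $X$ exactly and is
the tested path; the wall-clock probe times a fixed workload on the host
and is best-effort only. Under this model blockX is never slower than
either naive arrangement for any $n$ up to 4096 (verified exhaustively) and
is strictly better than block-first whenever $n$ is a multiple of 64 above
64. Wall-clock timings are recorded in benchmark output for orientation but
never asserted: they are hardware facts, not model facts.

# Model comparison

The final free energy of a converged inversion is the Laplace approximation
to the log model evidence. Fixed-effects group comparison sums log
evidences over subjects per candidate model and softmaxes the sums (after
subtracting the maximum, so arbitrarily large magnitudes are safe);
probabilities are invariant to adding a constant and to subject order. A
lead of 10 nats in the summed evidence already implies a posterior model
probability above 0.99. Random-effects comparison is out of scope.

# Synthetic data

`simulate_erp()` integrates a generating model, mixes it through a lead
field and adds Gaussian sensor noise. The signal-to-noise ratio is defined
on the trial-averaged response as peak signal power over noise power after
averaging; the generator calibrates the noise variance so the requested SNR
holds exactly in expectation (checked by Monte Carlo to within 10% over 200
replicates). Defaults mirror a typical averaged evoked-response recording:
250 Hz sampling and a 0–900 ms peristimulus window. Everything is
deterministic given the seed.

Two benchmark manipulations are provided. `extend_data_length()` tiles the
epoch along time and truncates — sample $k$ of the extended record equals
sample $k \bmod L$ of the original — so computational data-length scaling
can be studied without changing the data's statistics (typical sweep: 500 to
2500 samples). `scale_model_complexity()` grows the free-parameter count to
an exact target by enabling, in a fixed order, remaining forward, backward
and lateral connections, then condition modulations, then per-source
intrinsic log-deviations; if the target exceeds what distinct parameters
provide, duplicated-prior copies of the intrinsic deviations (plus one
partial copy) absorb the remainder, so any target at or above the base count
is reachable exactly (typical sweep: 46 to 256 parameters). Duplicated
copies act on the same constants, so they add workload and complexity
without changing the model family.

# The packaged studies

Two frozen studies exercise the pipeline end to end, sized to run on a
single CPU in a few minutes.

**Operating point.** Both use a near-rest firing sigmoid ($r = 2/3$,
$\eta = 1/3$) and stronger forward/backward baselines (128/64) with input
amplitude 5. The rationale is transmission: with the default far-threshold
sigmoid ($\eta = 6$ mV), the rest-point slope is 0.018, so each inter-areal
hop attenuates activity roughly fifty-fold and downstream sources respond at
$10^{-3}$ of the driven source — coupling parameters are then essentially
invisible to the data at any realistic SNR. The near-rest sigmoid is the
operating point commonly used by ERP model-fitting software precisely
because evoked-response hierarchies show downstream responses at a sizable
fraction of the driven response. This choice was made once, on sensitivity
grounds, when the studies were designed.

**Parameter recovery.** Two sources, forward 1→2 and backward 2→1, input to
source 1; truth $\theta_F = 0.4$, $\theta_B = -0.35$, input gain 0.1; 16
channels, 0–300 ms at 1 ms, SNR 10. The extrinsic log-scalings are required
to come back within 0.2 absolute of the truth.

**Group model selection.** Three sources in a forward chain with reciprocal
backward connections generate the data (subject noise seeds plus parameter
jitter of sd 0.1); candidates are the forward-only chain, the true
forward–backward chain and a chain with misplaced backward edges; 10
subjects, 8 channels, 0–240 ms at 2 ms, SNR 10, 10 replications. The
generating architecture is required to win fixed-effects BMS with
probability above 0.99 in at least 8 of 10 replications.

What these studies show — and what they do not: the synthetic data are
generated by the same model family that is fitted, with a known lead field,
stationary Gaussian sensor noise and no trial-level structure, artifacts,
filtering or head-model error. Passing them demonstrates the correctness
and calibration of the machinery, not that real EEG will identify the same
quantities as cleanly.

# Numerical choices and limitations

* Matrix exponentials use Padé scaling-and-squaring; posterior precisions
  are Cholesky-factorized, with a logged ridge when singular.
* Precision components are diagonal; arbitrary (e.g., temporally
  correlated) noise covariances are not supported.
* Conduction delays are omitted — the dynamics are a plain ODE system.
* Only the three-population source model is implemented; population
  targeting is configurable, but a four-population canonical-microcircuit
  variant is not provided.
* The wall-clock concurrency probe depends on the host and is not asserted
  anywhere; the simulated probe against the cost model is the tested path.
* Amplitudes are in arbitrary units end to end (lead fields are unit-norm by
  construction); only ratios — SNR, relative responses — are meaningful.
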