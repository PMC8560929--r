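---
title: "Model, inference and validation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, inference and validation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`vepmap` estimates the epileptogenic zone (EZ) of a seizure network by
inverting a generative model of SEEG log power. This vignette documents the
model and its assumptions, the tunable parameters, what the synthetic-data
generator does and does not emulate, the numerical choices, and the known
limitations. Nothing here reports numbers beyond what the test suite and
`scripts/acceptance.R` compute.

## The dynamical model

**Data-generating (5D) Epileptor.** Each brain region carries five state
variables on three timescales: a fast oscillatory pair $(x_1, y_1)$
producing ictal fast discharges, an intermediate pair $(x_2, y_2)$
producing spike-and-wave events, and a slow *permittivity* $z$ that gates
the transition between interictal and ictal states. Regions are coupled on
a structural connectome $C$ through the permittivity equation
($-K\sum_j C_{ij}(x_{1,j}-x_{1,i})$), so a seizing neighbour (elevated
$x_1$) pulls a region's $z$ downward, toward seizure. The low-pass
convolution term acting on the intermediate subsystem is realized as a
sixth state $u$ with $\dot u = x_1 - \gamma u$, which converts the integral
into an ODE so a one-step scheme applies. Constants: $\tau_0 = 2857$,
$\tau_2 = 10$, $I_1 = 3.1$, $I_2 = 0.45$, $\gamma = 0.01$.

An isolated node seizes autonomously when its excitability $x_0$ exceeds a
critical value near $-2.06$: at the fold of the fast nullcline
($x^\ast = -4/3$) the equilibrium loses stability. The package's
`seizure_threshold_2d()` recovers this boundary by bisection on simulated
trajectories; the test suite cross-checks it against the nullcline
geometry.

**Latent (2D) reduction.** For inference the fast subsystems are slaved
out, leaving per region the pair $(x, z)$ with
$\dot x = 1 - x^3 - 2x^2 - z + I_1$ and
$\dot z = (4(x - x_0) - z - \sum_j K C_{ij}(x_j - x_i))/\tau_0$.
Here $x$ is a proxy for the source log power: its depolarization shift
marks seizure onset, and $z$'s slow drift sets the onset time. Both models
share the same quiescent branch, so the reduction tracks the 5D slow flow.

## The generative model

Observed data are $D = (S, \vec\rho)$: the $T \times M$ log-power matrix
(T = 300 samples, M sensors) and each channel's total power (second sample
moment of its log-power series). The parameter vector
$\theta = (\vec x_0, \vec x(t_0), \vec z(t_0), K, \tau_0, \alpha, \beta,
\epsilon_1, \epsilon_2)$ has length $3N + 6$ (498 for the 164-region
Destrieux parcellation). Latent source states $Y$ follow the deterministic
2D flow: each observation interval advances the state by one RK4 step of
size 0.1 (substeps configurable), the deterministic limit of a Gaussian
state-transition density. The likelihood is Gaussian:
$s_i(t_j) \sim \mathcal N(\alpha \log\langle G_i, e^{\vec x(t_j)}\rangle +
\beta,\ \epsilon_1)$, with $G$ the source-to-sensor gain, and
$\rho_i \sim \mathcal N(\tfrac1T\sum_j \mu_{ij}^2,\ \epsilon_2)$ where
$\mu$ is the predicted log power.

Two modelling decisions here were genuinely open:

* **The total-power mean.** Conditioning $\rho$'s mean on the *observed*
  log power makes its residual identically zero and the posterior
  unbounded as $\epsilon_2 \to 0$ (the density $-M\log\epsilon_2$ grows
  without limit), which empirically derails the optimizer. We therefore
  use the second moment of the *predicted* log power, which also makes the
  fitted augmented feature a non-trivial model output.
* **Truncation of $\alpha$.** The amplitude scaling maps source log power
  to observed log power; a negative value is a polarity inversion with no
  physical reading, and the untruncated posterior contains a mirror mode
  that MAP occasionally falls into. $\alpha$ is therefore truncated below
  at zero, alongside $K$, $\tau_0$, $\epsilon_1$, $\epsilon_2$.

**Priors** (normal, SD in parentheses): hypothesis-conditioned
excitability $x_{0,i} \sim \mathcal N(-1.5, 1)$ inside the clinical EZ
hypothesis and $\mathcal N(-3, 1)$ outside — weakly informative, one SD
covering the distance from background to the seizure threshold; initial
states $x(t_0) \sim \mathcal N(-2, 10)$, $z(t_0) \sim \mathcal N(3.5, 10)$
near the quiescent fixed point; $K \sim \mathcal N(1, 10)$ (no assumed
connectivity scaling); $\tau_0 \sim \mathcal N(20, 10)$, a timescale at
which the latent transition is smooth on the 300-point grid;
$\alpha \sim \mathcal N(1, 10)$, $\beta \sim \mathcal N(0, 10)$,
$\epsilon_1, \epsilon_2 \sim \mathcal N(1, 10)$. Truncated densities carry
their half-line renormalization constant.

## MAP optimization

The unnormalized log posterior is maximized with L-BFGS
(`stats::optim`, memory 10, iteration cap 20 000 by default). Gradients
are exact: closed-form likelihood derivatives combined with a hand-derived
discrete adjoint of the RK4 chain, so the gradient differentiates the
actually computed objective rather than the continuous-time ideal; the
test suite verifies it against central finite differences at
`rtol = 1e-4`. Positive parameters are optimized through a log transform
*without* a Jacobian adjustment, so the optimum is the mode of the
natural-space density — the usual MAP semantics of probabilistic-programming
optimizers, and the convention under which a flat likelihood returns
exactly the prior means (a property the tests exercise).

Three convergence criteria are monitored: change in log posterior below
$10^{-12}$, gradient norm below $10^{-8}$, maximum parameter change below
$10^{-8}$ (per-coordinate, the stricter reading). Latent-state divergence
(any state magnitude above $10^3$) is absorbed as a large finite barrier
($10^{10}$, zero gradient) so the line search backtracks; `optim`'s
L-BFGS-B requires finite objective values, which rules out a literal
infinite penalty. Divergence at the initial point is an error suggesting a
different start. `vep_multistart()` draws initial vectors from normal
proposals centered at the prior means (truncations respected by
rejection) and keeps the run with the highest posterior.

## Feature extraction

Pipeline: zero-phase Butterworth high-pass → sliding-window mean square
(1 s window, 50% overlap) → natural log (floored at `rel_floor` of each
channel's peak power, default $10^{-6}$, a 60 dB dynamic-range cap) →
zero-phase low-pass smoothing → resampling to exactly 300 points. Filters
use odd-reflection padding; window centers stay one window clear of the
recording edges. Defaults are order-2 Butterworth (doubled in effective
order by the forward-backward pass; higher orders are numerically marginal
at the low normalized cutoffs of long recordings).

The high-pass cutoff is relative to where the model's discharges live. For
patient-style recordings the convention is 10 Hz. The bundled synthetic
scenario maps one model time unit to 0.1 s, which places Epileptor
discharges at 2–3 Hz, so the synthetic pipeline (`dataset_features()`)
uses a 1 Hz high-pass and a stronger envelope smoother
(`lp_frac = 0.065`) — the same role as the per-patient smoothing tuning of
clinical workflows, which exists to suppress short interictal spikes that
the envelope model would otherwise chase.

Two inversion-side normalizations compensate for structure the observation
model cannot represent (it has a single global offset $\beta$):
gain rows are normalized to unit sum (within-row relative weights, which
carry the attribution information, are unchanged), and each channel's
median log power is subtracted. Channel baselines are set by background
activity mixing *incoherently* at the sensor, while the model predicts a
coherent projection; without these steps the fit manufactures spurious
tonically-active sources to flatten predicted baselines. Both are options
of `vep_observation()` and on by default. Finally, fitting uses a
seizure-centered clip (default 20–160 s of the bundled scenario's
recording), as clinical fits use the ictal clip rather than the whole
record; this also aligns the data's onset position with the prior's
natural transition time.

## The synthetic-data generator

The generator emulates a focal seizure recorded by depth electrodes:

* **Scenario.** Two EZ regions at $x_0 = -1.8$, four strongly connected PZ
  regions at $-2.3$, all others at $-3.0$; Heun integration with
  $dt = 0.04$ for 2500 time units (plus a discarded 300-unit burn-in that
  lets the intermediate subsystem settle). Under the defaults exactly the
  six seizing regions are recruited and every EZ onset precedes every PZ
  onset.
* **Connectome.** Background weights $U(0, 0.02)$, EZ–PZ weights near 1,
  max-normalized. Heterogeneity is essential, not cosmetic: the
  permittivity coupling is diffusive, so a dense strong background anchors
  every node to the network mean, suppressing both autonomous seizing and
  recruitment. The global coupling default $K = 0.7$ and the initial
  permittivity $z(0) = 3.3$ (a pre-ictal start; the deep interictal
  equilibrium would spend most of the window on slow relaxation) were set
  once by analyzing simulations so that the scenario reproduces its
  intended recruitment pattern, in the same spirit as tuning a simulation
  until it expresses the phenomenon under study.
* **Geometry.** Region centroids in a 100-unit cube with small vertex
  clouds; two SEEG contacts per seizing region at 3.5–4.5 units plus
  distant contacts, mimicking implantation in the vicinity of the
  suspected focus with uniform contact quality.
* **Noise.** Additive dynamic noise on the intermediate subsystem
  (SD 0.025), as in stochastic whole-brain simulators — it provides the
  ongoing background activity and sustained ictal discharges that a fully
  deterministic run lacks. A first-order 0.16 Hz high-pass emulates the
  acquisition hardware's band-pass; without it the slow ictal baseline
  shift dominates channel variance and the nominal observation SNR becomes
  meaningless in the envelope domain. Observation noise is zero-mean
  Gaussian with a single SD chosen so the channel-averaged
  variance ratio equals the target SNR.

What the generator does **not** emulate: tractography-derived connectomes
(and their distance-dependent weight profile), spatially extended cortical
sources with orientation effects, bipolar montages, artifacts, multiple
seizures per record, or inter-patient variability. Passing tests therefore
demonstrate internal consistency of the method under its own forward
model at reduced scale — not clinical performance.

## Validation protocols and problem sizes

The acceptance tests run scaled-down replicas of the reference protocols,
sized for a desktop run: the recruitment and noiseless-recovery checks use
a 24-region network with 16 contacts; the robustness sweeps use 12 regions
with 12 contacts, 4 replicates per SNR level (grid 0.1–2.5), and 4 starts
per proposal SD (grid 0.1–1.0), with the optimizer capped at 2000
iterations per fit. The SNR sweep locates the critical SNR for perfect EZ
recovery via the midpoint between the largest failing and smallest
succeeding level. At this scale the initialization sweep reproduces the
qualitative regimes — tight proposals always recover, wide proposals fall
into local minima — but the degradation sets in at smaller proposal SDs
than in the full-scale reference protocol; the reduced problem's posterior
is rougher, and the all-or-nothing degradation estimator is pessimistic at
small start counts.

## Known limitations

* MAP provides a point estimate only; no posterior uncertainty (full
  sampling over the ODE-constrained posterior is out of scope).
* The EZ/PZ split is sensitive to the onset tolerance $t_\epsilon$ when
  inferred onsets of co-onsetting regions jitter by about the tolerance;
  the `t_epsilon` sweep in `run_evaluate()` makes this explicit.
* The structural non-identifiability between excitability patterns that
  generate similar latent flows is not reparameterized away; labels should
  be read from the latent trajectories (onsets), not from raw $x_0$
  magnitudes.
* Time is dimensionless model time; mapping to seconds is a labeling
  convention of the scenario (`seconds_per_unit`), and all tolerances are
  interpreted on that axis.
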