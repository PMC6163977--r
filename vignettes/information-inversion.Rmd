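---
title: "Information-density inversion for viscoelastic characterization: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-density inversion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes and why the
numerical choices are what they are.  It is written for a user who wants to
trust (or challenge) the results, not just obtain them.

## 1. The inference framework

All uncertain quantities — observations $O$, constitutive parameters $M$,
model hypotheses $H$, design variables $S$ — carry *information densities*:
nonnegative, deliberately unnormalized plausibility functions $f(\cdot)$
that are zero exactly where a value is impossible.  Two independent sources
of information about the same space combine by the logical operations

$$\{f_1 \:\mathrm{and}\: f_2\} = f_1 f_2, \qquad
  \{f_1 \:\mathrm{or}\: f_2\} = f_1 + f_2 .$$

Inference is conjunction: the experimental density (centred on the measured
strains) is multiplied by the model density (centred on the simulated
strains), and the latent observation space is marginalized out.  Dropping
the normalization axiom means no Bayes denominator ever appears during
parameter reconstruction; a single rescaling at the end recovers classical
probabilities when they are wanted.  `test-information_core.R` verifies
that this route coincides pointwise (to $10^{-10}$ relative) with the
Bayesian posterior under a Gaussian likelihood and a uniform prior on the
normalized parameter cube — the two formulations differ by a constant only.

**Jeffreys parametrization.**  Every constitutive parameter here (shear
modulus, viscosity, Landau coefficients) is strictly positive and as
naturally quoted as its reciprocal (stiffness vs compliance).  A
noninformative density can only be simultaneously constant for the
parameter and its reciprocal in logarithmic coordinates, so each parameter
is mapped by
$$\tilde m = \frac{\ln (m/m_{\inf})}{\ln (m_{\sup}/m_{\inf})} \in [0,1]$$
and all sampling, histogramming and integration happen on the unit cube.
The reciprocal-mirror identity $\tilde m(1/m) = 1 - \tilde m(m)$ is tested
as a property.

**Gaussian particularization.**  With independent Gaussian measurement
noise (covariance $C^o$) and optionally Gaussian model error ($C^m$, zero
by default since numerical error is negligible against sensor noise), the
conjunction collapses to $f(M) \propto e^{-J}$ with the quadratic misfit
$$J = \tfrac12 \sum_{ij} (\epsilon^{sim}_i - \epsilon^{obs}_i)\,
      [(C^o + C^m)^{-1}]_{ij}\,(\epsilon^{sim}_j - \epsilon^{obs}_j).$$

*Convention:* $J$ is a plain sum over the recorded sample instants, with no
$\Delta t$ weighting.  The compound information of independent samples is
the product of per-sample densities, which is a sum inside the exponential;
a $\Delta t$ factor would uniformly rescale $J$ and silently change
evidence ratios between designs with different sample counts, so the
convention is fixed here once and documented.  Consequences of this choice
are visible in the design scan (Section 5).

## 2. The constitutive hypotheses

Five scalar laws for a stress-controlled uniaxial test, all of the form
$\epsilon = \epsilon_e(\sigma) + \epsilon_v(t)$:

* **H1** $\sigma = \mu\epsilon_e + A\epsilon_e^2$, $\dot\epsilon_v = \sigma/\eta$ — parameters $\{\mu, \eta, A\}$;
* **H2** linear spring, $\{\mu, \eta\}$;
* **H3** linear elastic only, $\{\mu\}$;
* **H4** adds $D\epsilon_e^3$, $\{\mu, \eta, A, D\}$;
* **H5** H1 with the phenomenological substitution $\eta(t) = 3\mu t$, $\{\mu, A\}$.

The strain in these laws is treated as the scalar work-conjugate of the
applied stress; nothing in the mathematics requires distinguishing shear
from engineering strain for a uniaxial scalar test.

**Numerics.**  The elastic strain is the root of the Landau polynomial
continuous with the linear solution $\sigma/\mu$, found by safeguarded
Newton started at $\sigma/\mu$ and bracketed in $[0, \sigma/\mu]$ (the
polynomial is increasing and convex there for nonnegative coefficients, so
the root is unique; non-convergence is recorded as an impossible
evaluation, $J = +\infty$, never an abort).  The viscous strain is a pure
quadrature of the known stress history, so the ODE is integrated by the
trapezoidal (Heun) rule on a fine grid, default $10^{-3}$ s — second order
is ample, and the grid is forced to contain the ramp reversal so the kink
costs no accuracy.  For H5 the rate $\sigma(t)/(3\mu t)$ has a removable
singularity at $t = 0$ (the ramp makes $\sigma/t$ finite); the quadrature
starts from that limit value.  H5 is implemented as a hard substitution of
$\eta(t)$ into the H1 dynamics: the alternative reading — a density
conjunction over an uncertain $\eta$ — has no executable form without
inventing a spread for the phenomenological law, so the substitution is
the only self-contained choice.

Nesting identities (H4 with $D = 0$ equals H1; H1 with $A \to 0$ equals
H2; H2 approaches H3 as $\eta \to \infty$), integrator convergence order,
and loading/unloading hysteresis are all enforced by property tests.

## 3. The synthetic experiment and the noise model

The generator reproduces the package's reference study: truth H1 with
$\mu = 1$ MPa, $\eta = 10$ MPa·s, $A = 15$ kPa; triangular stress 0 → 1 MPa
→ 0 over $2T = 2$ s; strain sampled every 0.1 s (21 data); i.i.d. Gaussian
noise.  Per-sample noise variances are recorded in the observation set and
reused as $C^o$, so inference on generated data is self-consistent; for
external data the user must supply variances.

Three noise conventions are implemented, and the choice matters more than
any other configuration:

* **stress-equivalent** (default): a sensor error quoted on the load scale,
  $sd_\sigma = 10$ kPa, mapped through the linear compliance to
  $sd_\epsilon = sd_\sigma/\mu = 0.01$;
* **relative**: $sd_i = 0.1\,|\epsilon_i|$ per datum, floored at $10^{-3}$;
* **absolute-strain**: constant $sd_i$.

The default was fixed by identifiability, not convenience.  The quadratic
nonlinearity shifts the strain by at most $A\epsilon^2/\mu \approx 1.5\%$
at the reference truth.  Under 10%-relative noise (strain sd up to 0.1)
that signal is invisible: the posterior for $A$ degenerates to the prior
and no procedure can claim to estimate it.  Under the 10 kPa
stress-equivalent reading the nonlinearity sits at the noise floor and all
three parameters are recoverable — which is the regime this package's
reference experiment is meant to demonstrate, including the strong negative
$\mu$–$A$ posterior correlation visible in `joint_slice_2d()`.  Both other
modes remain available and tested.

## 4. Reconstruction, marginals, and the mode estimator

`reconstruct()` draws $N = 2^{16}$ uniform points on the hypothesis's unit
cube (plain Monte Carlo — deliberately no importance sampling or MCMC, to
keep the evidence estimator the unweighted mean that the rest of the
machinery reuses), runs the forward model at each, and stores $J$ and
$e^{-J}$.  Evidence integrals accumulate in the log domain
($I = e^{-J_{\min}}\,\overline{e^{-(J - J_{\min})}}$) so they survive
arbitrarily large misfits.

Marginals are weighted histograms over the normalized coordinate, 64 bins,
area-normalized.  Point summaries:

* **median / sd** — weighted quantile and weighted standard deviation of
  the physical values;
* **mode** — the peak of a boundary-reflected Gaussian kernel density
  estimate whose Silverman bandwidth uses the *effective* sample size
  (Kish, $(\sum w)^2/\sum w^2$) in place of $n$.

The KDE mode deserves its justification.  At the reference conditions the
posterior mass concentrates in a tiny fraction of the cube, so $2^{16}$
plain-MC points yield an effective sample size of order 10; meanwhile the
$\mu$ posterior is *narrower than a single 64-bin histogram bin*, so the
raw smoothed-histogram peak carries a guaranteed half-bin quantization bias
(≈ 3.5% in $\mu$ for decade-wide bounds) that exceeds the posterior spread
itself.  The adaptive-bandwidth KDE resolves sharp marginals below the bin
width and, at the other extreme, smooths weakly informed marginals instead
of echoing the coordinate of a single heavy sample.  The histogram curve
and its smoothed peak remain exposed (`density`, `density_smooth`, attribute
`mode_hist`) for users who want the cruder estimator.

Degenerate inputs are handled explicitly: all-zero weights signal
falsification as an error; exact ties in the maximum-weight sample break
to the lowest index so seeded runs are fully deterministic.

## 5. Hypothesis ranking and design optimization

Because every hypothesis's noninformative density has unit mass on its own
cube, evidences $I_k$ of different dimensionality are directly comparable
and $p(H_k) = f_o(H_k) I_k / \sum_j f_o(H_j) I_j$.  A parameter absent from
a hypothesis is never "set to zero" — it simply carries no density factor.
Extra dimensions that do not pay for themselves in fit dilute the
integrand: the Occam penalty requires no extra term.  Each hypothesis uses
its own RNG stream derived from the user seed, so rankings are reproducible
while streams stay independent.

Two honest caveats, both visible in the acceptance suite rather than hidden:

* At the reference noise level the H1-vs-H2 evidence gap
  ($\Delta J \approx 2\text{–}3$ at best fit) is comparable to H1's Occam
  dilution over the $A$ axis, so the generating model H1 outranks H2 only
  in about half of noise realizations; the clearly wrong H3 and H5 are
  falsified outright every time.  A decisive H1 preference requires noise
  roughly an order of magnitude smaller (the consistency test in
  `test-model_selection.R` checks exactly that limit).
* The evidence estimator's Monte-Carlo standard error at effective sample
  size ~10 is ≈ 30%, which occasionally flips near-tied rankings between
  seeds.

**Design scan.**  Before any experiment exists, "the experiment at design
$T$" is synthesized from the reference truth: triangular protocol rescaled
to half-duration $T$, sampling interval kept at 0.1 s, noise per the
configured spec, 8 independent noise replicates averaged per design to tame
scan variance.  The gain $f(T)$ is the evidence $I(T)$, normalized over the
grid into $p(T)$; both the pointwise terms $p \log_b p$ and the signed
total entropy $-\sum p \log_b p$ are reported (base 2, $e$ or 10 — bits,
nats, hartleys), since the pointwise quantity alone is not Shannon entropy
and users should see both.  The optimum is the $\arg\max$ of $p(T)$, ties
resolving to the shortest (cheapest) test.

With the plain-sum misfit convention, each additional sample contributes
$\approx \tfrac12$ to the expected best-fit misfit, so $I(T)$ carries an
$e^{-n(T)/2}$ factor and the scan is monotone decreasing in $T$ at fixed
$\Delta t$: the shortest test in the range wins.  Alternative readings were
examined (holding the sample count fixed while scaling $\Delta t$; scoring
designs on noiseless synthesized data, where $I(T)$ measures pure posterior
volume; scoring on the uncertainty reduction $-\log I$): none produces an
interior optimum — they move the winner to one end of the range or drown it
in replicate noise.  The package therefore reports the scan exactly as
defined and leaves the interpretation of "gain" configurable through the
noise and protocol settings rather than hard-coding a preferred answer.

## 6. Default configuration and problem sizes

| quantity | default | unit | why |
|---|---|---|---|
| bounds $\mu$ | [0.1, 10] | MPa | one decade either side of the reference truth |
| bounds $\eta$ | [1, 100] | MPa·s | idem |
| bounds $A$, $D$ | [1.5, 150] | kPa | idem |
| $N$ (MC samples) | $2^{16}$ | — | seconds-scale runtime at full fidelity |
| histogram bins | 64 | — | ~$10^3$ raw samples per bin at $2^{16}$ |
| KDE mass grid | 1024 | — | resolves sharp marginals to $10^{-3}$ in coordinate |
| integration step | $10^{-3}$ | s | trapezoid error far below noise |
| noise | stress-equivalent 10 | kPa | identifiability (Section 3) |
| design grid | 25 log-spaced in [0.2, 5] | s | scan range of the reference study |
| replicates per design | 8 | — | tames evidence variance |

Bounds are centred log-symmetrically on the reference truth so the truth
sits at the cube centre; they are the single most influential free choice
(evidence values scale with prior volume) and are fully configurable per
run.  The test suite and the acceptance script run these exact sizes; a
full reconstruction takes ~2 s and the complete design scan ~1 min on one
core.

## 7. What the generator does and does not emulate

The synthetic experiment reproduces: the triangular stress-controlled
protocol, sampling cadence, i.i.d. Gaussian sensor noise with recorded
variances, and seeded reproducibility (every generated set regenerates
bit-identically from its provenance record).  It does **not** emulate
correlated or drifting sensor error, stress-axis uncertainty, specimen
geometry effects, temperature dependence, or model discrepancy (the truth
is always one of the five hypotheses).  Passing tests therefore demonstrate
the correctness and calibration of the *inference machinery* under the
stated noise model — not robustness of the constitutive conclusions on real
instrument data, where $C^o$ must come from the instrument and $C^m$ may no
longer be negligible.

## 8. Known limitations

* Plain Monte Carlo with $2^{16}$ points leaves an effective sample size of
  order 10 at the reference noise level; marginal summaries for weakly
  identified parameters (the nonlinearity $A$, whose posterior is a plateau
  spanning everything below ≈ 20 kPa) inherit that scatter across seeds.
* Evidences depend on the chosen parameter bounds through the prior volume;
  rankings should be read conditional on those bounds.
* The design scan's scalar grid covers a single design variable (duration);
  the data structures allow more, but no multi-dimensional search is
  implemented.
* Non-Gaussian observation densities are admitted by the framework but not
  implemented; only the Gaussian particularization is.
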