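---
title: "Decoupling intrinsic selection from ecological interactions in two-type games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoupling intrinsic selection from ecological interactions in two-type games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoevogames)
```

## The model

Consider a wild-type and a mutant population competing in a well-mixed
culture. Interactions are summarised by a symmetric two-strategy game with
payoff (per-generation growth) matrix

$$P = \begin{pmatrix} a & b \\ c & d \end{pmatrix},$$

where rows are the focal type (wild-type first) and columns the opponent
type. Requiring each row to be constant when ecological interactions are
absent forces the additive decomposition used throughout this package:
after normalizing the wild-type reference growth to 1 (dividing all
entries by $a$, which preserves the fitness ratios that selection acts
on),

$$P = \begin{pmatrix} 1 & 1 + \alpha_{wm} \\
      1 + s_m + \alpha_{mw} & 1 + s_m \end{pmatrix}.$$

Here $s_m$ is the **intrinsic** (monoculture) selection coefficient of
the mutant, $\alpha_{wm}$ is the growth-rate modification of the
wild-type caused by the mutant, and $\alpha_{mw}$ the modification of the
mutant caused by the wild-type. All three are dimensionless. The
multiplicative alternative (normalizing by subtraction, or decomposing
rows multiplicatively) was rejected: it is incompatible with the regime
conditions below, all four of which verify symbolically only under the
additive form.

With mutant fraction $x$, the expected fitnesses are
$f_w(x) = 1 + \alpha_{wm} x$ and
$f_m(x) = 1 + s_m + \alpha_{mw}(1 - x)$, and the **frequency-dependent
selection coefficient** is the relative advantage

$$\sigma_m(x) = \frac{f_m(x) - f_w(x)}{f_w(x)}
  = \frac{s_m + \alpha_{mw} - (\alpha_{wm} + \alpha_{mw})\,x}
         {1 + \alpha_{wm}\,x},$$

which reduces to $s_m$ when both interaction coefficients vanish. The
replicator equation is
$\dot x = x(1-x)\,[\,(c-a)(1-x) - (b-d)x\,] = x(1-x)\,(f_m - f_w)$, with
stationary points at 0, 1 and, when admissible, at
$(s_m + \alpha_{mw}) / (\alpha_{wm} + \alpha_{mw})$.

```{r}
dec <- decompose_payoff(normalize_payoff(payoff_matrix(2, 2.4, 2.8, 2.2)))
dec
fixed_points(dec)
```

## The four interaction regimes

Ecological interactions can leave intrinsic selection apparently
untouched or completely reshape it. Four named regimes formalize this:

* **maintenance** — $\sigma_m(x) = s_m$: interactions present but the
  dynamics match the non-interacting system;
* **masking** — $\sigma_m(x) = 0$ with $s_m \ne 0$: a real monoculture
  fitness difference is neutralized in co-culture;
* **mirroring** — $\sigma_m(x) = -s_m$: the selective advantage is
  inverted, same magnitude, opposite direction;
* **mimicry** — $s_m = 0$ but $\sigma_m(x) = s' \ne 0$: equally fit
  monocultures behave as if one were selected in co-culture.

In the deterministic framework, requiring the identity to hold for *all*
$x$ (clear the positive denominator and match polynomial coefficients in
$x$) gives one coefficient pair per regime, e.g. $(\alpha_{mw},
\alpha_{wm}) = (-s_m, s_m)$ for masking and the trivial $(0, 0)$ as the
only maintenance solution:

```{r}
regime_coefficients_deterministic("masking", s_m = 0.3)
regime_coefficients_deterministic("mirroring", s_m = 0.2)
```

Because $\dot x = x(1-x)\sigma_m(x) f_w(x)$, a regime pair with
$\alpha_{wm} \ne 0$ reproduces the non-interacting *orbit* exactly but
runs on a rescaled clock (the positive factor $f_w(x)$); the package
tests assert both the $\sigma$-identity and this time-rescaled orbit
equivalence, and pointwise-in-time equality where $\alpha_{wm} = 0$.

## Mutation, drift, and regimes at the stationary mode

Real populations are finite and mutate. With symmetric per-generation
mutation rate $\mu$ and constant selection $\sigma$, the mode of the
stationary frequency distribution sits at the mutation-selection balance
root of $\sigma x(1-x) + \mu(1-2x) = 0$:

$$x_{mode} = \frac{\sigma - 2\mu + R}{2\sigma}, \qquad
  R = \sqrt{\sigma^2 + 4\mu^2},$$

computed internally in the cancellation-free form
$2\mu / (R + 2\mu - \sigma)$, which is continuous through $\sigma = 0$
(value $1/2$) and valid for either sign of $\sigma$. The stochastic
regimes are defined by evaluating $\sigma_m$ at the $x_{mode}$ of the
regime's *target* reference system (maintenance at $x_{mode}(s_m)$,
masking at $1/2$, mirroring at $x_{mode}(-s_m)$, mimicry at
$x_{mode}(s')$) and demanding it equal the target. Substituting
$x_{mode}$ into $\sigma_m$ and scaling numerator and denominator by
$2 s_m$ yields the closed form implemented in `sigma_at_mode()`; the
package derives it by exact substitution, under which the identity with
direct evaluation holds to machine precision for both signs of $s_m$
(`sgn`-based rearrangements that treat the two signs asymmetrically do
not survive this check for $s_m < 0$). At $s_m = 0$ the two-sided limit
(evaluation at $1/2$) is used; `sgn(0) = 0` conventions give an
inconsistent value.

Expanding each implicit condition to first order in $\mu$ gives the
closed-form regime surfaces of `stochastic_surface_first_order()`;
`stochastic_surface_exact()` solves the implicit condition by bracketed
root finding and serves as the reference. Two numerical facts are worth
recording:

* the masking surface $\alpha_{wm} = \alpha_{mw} + 2 s_m$ is *exactly*
  linear and independent of $\mu$ (the reference mode is $1/2$), so both
  solvers coincide to rounding;
* for maintenance, mirroring and mimicry the $\mu^2$ coefficient of the
  first-order truncation error vanishes identically, so the first-order
  surfaces converge to the exact ones at rate $\mu^3$ — faster than the
  nominal first-order truncation would suggest. The tests therefore
  assert *at least* quadratic convergence (measured log-log slope
  $\approx 3$).

```{r}
stochastic_surface_first_order("maintenance", s_m = 0.1, mu = 1e-3, free = 0.5)
stochastic_surface_exact("maintenance", s_m = 0.1, mu = 1e-3, free = 0.5)
```

Rearranging the mirroring condition for $\alpha_{wm}$ instead of
$\alpha_{mw}$ introduces a term of order $\mu^{-1}$; the package
therefore solves mirroring for $\alpha_{mw}$ given $\alpha_{wm}$.

## The Wright-Fisher engine

`run_replicate()` simulates a haploid population of fixed size $N$ with
non-overlapping generations. The event order per generation — not fully
pinned down in standard descriptions of frequency-dependent
Wright-Fisher models — is fixed here as: selection weighting
$p^* = x f_m / (x f_m + (1-x) f_w)$, then symmetric mutation of the
expected frequency $p^{**} = p^*(1 - 2\mu) + \mu$, then one binomial
draw of size $N$. Mutation acts on the expected frequency rather than
per individual; the mean is identical and the variance difference is
negligible at the population sizes used here. The transition matrix in
`wf_stationary_distribution()` uses the *identical* order, so chain and
simulator describe the same process; the stationary law is obtained by a
direct linear solve of the $(N+1)$-state balance equations rather than
an assumed diffusion limit. The state is an integer count, not a
floating-point fraction, so trajectories are exactly reproducible;
per-replicate seeds derive from the master seed by a counter scheme,
making ensembles independent of evaluation order.

Two types make the multinomial resampling a binomial. Under the
deterministic masking pair, $f_m \equiv f_w$ implies $p^* = x$ at every
state, so the masked simulator is *bit-identical* to the neutral one
under shared seeds — the strongest form of the masking claim, and a
property the tests assert directly.

The ensemble protocol (defaults of `sim_params()`) starts replicates at
a 50:50 mix, discards 1000 burn-in generations, averages the next 3000,
and uses 50 replicates. Mode estimates from pooled samples use a
101-bin histogram with exact ties broken toward the analytic prediction
under test (ties are reported). Problem sizes in the test suite are
chosen for statistical resolution rather than realism of a single
experiment:

* the neutral-mode simulation check uses $N = 10^4$, $\mu = 10^{-2}$
  (so $2N\mu = 200$ and the stationary law has sd $\approx 0.025$) with
  $1.6 \times 10^6$ pooled post-burn-in samples, sized so the histogram
  argmax standard error is well below one bin;
* the simulator-versus-chain total-variation comparison pools
  $8 \times 10^6$ samples across 500 replicates: with an autocorrelation
  time of order $1/(2\mu)$ generations, smaller pools are dominated by
  sampling noise across the ~200 occupied states and cannot certify a
  0.05 total-variation bound;
* the mirroring-inversion ensemble comparison extracts each replicate's
  final fraction after 1000 generations instead of time-averaging:
  the mode-level theory leaves an $O(\mu)$ asymmetry between the
  stationary *means* of the mirrored and reflected systems, and time averaging
  would shrink the standard error below that model-level remainder,
  turning an agreement check into a test of a claim the theory does not
  make.

## Inferring games from growth assays

`fit_growth_frequency()` regresses each type's per-capita growth rate on
the seeding mutant fraction (wild-type monoculture at $x = 0$, mutant
monoculture at $x = 1$), by unweighted ordinary least squares (a
replicate-weighted option exists). The payoff entries are the line
values at the boundaries: $a, b$ from the wild-type line at $x = 0, 1$
and $c, d$ from the mutant line. Linear frequency dependence is a model
assumption; a quadratic curvature check warns at the 0.05 level when it
is violated. The synthetic assay generator draws Gaussian measurement
noise around the payoff-implied lines; its defaults (five seeding
fractions spanning $[0, 1]$, noise sd 0.02 on growth rates of order 1,
a few replicates) emulate a careful plate-reader game assay. What it
does *not* emulate: non-linear frequency dependence, shared batch
effects between the two types' measurements, growth-phase (lag/saturation)
artefacts, and seeding-fraction error. Passing recovery tests therefore
certify the estimator under the model, not robustness to those
violations.

Payoff tables with non-positive reference growth $a \le 0$ cannot be
normalized by this scheme and are rejected row-wise with diagnostics
rather than silently dropped. The boundary convention $b = 0$
($\alpha_{wm} = -1$), used by some published payoff estimates, is
admitted and flagged, although it makes the wild-type fitness vanish in
an all-mutant population.

## Distances to the regime surfaces

For a measured $(s_m, \alpha_{mw}, \alpha_{wm})$, `project_to_surface()`
minimizes the unitless Euclidean distance to the maintenance, masking or
mirroring surface with $\mu$ frozen at 0.001 (the value used when
scoring experimental systems; $\mu$ is a fixed parameter, not a
coordinate). No rescaling of the three coordinates is applied beyond
their intrinsic dimensionlessness. Mimicry is excluded: its target
selection coefficient is arbitrary. First-order surfaces are the
default target; the exact surfaces sit behind `method = "exact"`.

At fixed $s_m$ every surface is a straight line in the
$(\alpha_{mw}, \alpha_{wm})$ plane, so the squared distance profiles
over $s_m$ in closed form. The minimizer scans that profile on a dense
grid (linear plus log-spaced points near $s_m = 0$, where the
maintenance and mirroring surfaces have a singular sheet on which the
constrained coefficient diverges), adds the roots where the fixed-$s_m$
line interpolates the query point (dips in the profile narrower than
any fixed grid), refines candidates in one dimension, and polishes the
best with a quasi-Newton optimization of the full two-parameter
objective. A generic Latin-hypercube multi-start was rejected: it
reliably misses the singular sheet, returning distances larger than a
dense-grid brute force. Non-convergence across all candidates yields a
flagged failure result, never a silent zero. The masking surface is a
plane, giving the closed-form oracle $|\alpha_{wm} - \alpha_{mw} -
2 s_m| / \sqrt{6}$ used in the tests.

```{r}
project_to_surface("masking", c(0.1, 0.3, 0.6))
```

One modelling caveat inherited from the singular sheet: a measured point
with small $|s_m|$ can project onto a surface point with a tiny $s_m$ of
the *opposite* sign and a large constrained coefficient. That is the
faithful minimizer of the stated objective, but distances to the
maintenance and mirroring surfaces for near-neutral systems should be
interpreted with care (and records with $s_m = 0$ exactly are excluded,
as those surfaces are singular there).

## Numerical choices and degenerate inputs

* Replicator integration: `deSolve::ode` (lsoda) at absolute and
  relative tolerance $10^{-10}$, states clipped to $[0, 1]$.
* Constancy of $\sigma_m(x)$ is decided by polynomial-coefficient
  matching after clearing the denominator (tolerance $10^{-9}$), not by
  grid evaluation.
* Fully degenerate games (the masking family, including the neutral
  game) have identically zero replicator velocity: fixed-point analysis
  returns a degenerate marker and steady-state classification returns
  `"none"` with a diagnostic instead of inventing an outcome.
* Exact zeros of the game-space coordinates classify as `"boundary"`
  rather than being absorbed into a quadrant; $s_m = 0$ makes the
  interaction-selection point undefined (flagged, not an error).
* Quadrant boundaries follow the coexistence definition
  $\alpha_{wm} > s_m$, $\alpha_{mw} > -s_m$ (equivalently the signs of
  $c - a$ and $b - d$); the interaction-selection plot axes are
  $(\alpha_{mw}/s_m, \alpha_{wm}/s_m)$ in that order.
* `sigma_at_mode()` errors on the measure-zero parameter set where its
  denominator vanishes rather than returning an unstable value.

## Limitations

The framework is strictly two-type: no $n > 2$ strategy games, no
Lotka-Volterra/carrying-capacity extensions, no asymmetric mutation
rates, and no demographic fluctuation of $N$. Regime definitions in the
stochastic setting are statements about the stationary *mode*;
higher moments (variance, skew) can differ between systems whose modes
agree and are not treated here. Inference from assays assumes linear
frequency dependence and independent Gaussian noise.
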