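---
title: "Multistate free energies by replica-exchange enveloping distribution sampling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate free energies by replica-exchange enveloping distribution sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reedsim)
```

## The model

Given $N$ end-state potentials $V_i(\mathbf r)$ (in the alchemical picture:
one ligand active, the others dummies), enveloping distribution sampling
(EDS) defines a single reference Hamiltonian

$$
V_R(\mathbf r; s, \mathbf E^R) \;=\; -\frac{1}{\beta s}
\ln \sum_{i=1}^{N} e^{-\beta s \,\left(V_i(\mathbf r) - E_i^R\right)},
\qquad \beta = (k_B T)^{-1},
$$

a smoothed soft-minimum of the shifted end states. Two parameter families
tune it:

* the **smoothing parameter** $s \in (0, 1]$. At $s = 1$ the reference
  landscape retains every end-state minimum, separated by the original
  barriers; as $s$ decreases the barriers flatten, until in the
  *undersampling* regime all states contribute equally and the reference
  acquires a single unphysical minimum. Useful bounds (asserted as package
  invariants): $\min_i(V_i - E_i) - \ln N /(\beta s) \le V_R \le
  \min_i(V_i - E_i)$, and $V_R$ is non-increasing as $s$ decreases.
* the **energy offsets** $E_i^R$ (kJ/mol). At their optimum they equal the
  states' free energies, which makes every state an equal contributor.
  Because offsets enter as $V_i - E_i$, adding a constant to all of them
  lowers $V_R$ by that constant and changes nothing physical; offsets are
  therefore reported pinned to state 1 = 0.

Replica exchange over a descending ladder of $s$-values (RE-EDS) couples a
physical replica at $s = 1$, from which all free energies are read, to
undersampling replicas that shuttle configurations between the end-state
minima. Neighbour swaps use the standard Metropolis–Hastings criterion on
the cross-evaluated reference Hamiltonians; free-energy differences follow
from double Zwanzig estimation through the sampled reference,
$\Delta G_{ji} = -\beta^{-1}(\ln\langle e^{-\beta (V_j - V_R)}\rangle_R -
\ln\langle e^{-\beta (V_i - V_R)}\rangle_R)$. All $N(N-1)/2$ differences
come from one vector of log-averaged weights, so the matrix is exactly
antisymmetric and every thermodynamic cycle closes to machine precision by
construction — a property the test suite asserts at $10^{-10}$ kJ/mol.

## What the toy systems emulate — and what they do not

The package replaces molecular end states with analytic toys: harmonic
oscillators in 1–3 dimensions and one-dimensional multi-well polynomials.
Harmonic states have closed-form free energies
($\Delta G_{ji} = \Delta c + \tfrac{1}{2\beta}\sum_d \ln (k_{j,d}/k_{i,d})$),
and any 1D pair can be cross-checked by adaptive quadrature of the
Boltzmann integrals; these oracles sit underneath every estimator test.

The default benchmark (`toy_benchmark()`) has five 1D harmonic states with
minima across 1 nm, force constants between 500 and 5000 kJ/mol/nm² and
energy shifts between −80 and +20 kJ/mol, so the offset machinery is
exercised over free-energy gaps of the size met in real ligand series. The
bottleneck preset (`toy_bottleneck()`) clusters the minima in two groups
2 nm apart, which opens an exchange gap at intermediate $s$ — the situation
the ladder optimizer exists to repair.

What the toys do *not* emulate: solvent and conformational relaxation,
rugged landscapes, kinetic trapping beyond a single coordinate, and the
favourable phase-space overlap that chemically similar ligands share. In
particular, the initial offset estimate (below) is *harder* on these toys
than on molecular systems, because narrow wells far apart overlap poorly
with the averaged undersampling ensemble. Passing tests therefore
demonstrate correctness of the machinery and robustness of the
parameter-fixing loop, not MD-scale accuracy claims.

## The automated pipeline

The workflow (`run_workflow()`) has four stages.

**1–2. Exploration.** A short run over 21 log-spaced $s$-values in
$[1, 10^{-5}]$ with zero offsets yields (i) per-state undersampling
thresholds $T_i^{us}$, taken as the 0.95 quantile of $V_i - E_i$ in the
lowest-$s$ replica, and (ii) the ladder lower bound: a replica is
undersampling when every state's occurrence fraction against $T^{us}$
reaches 0.75, and the bound is set two ladder levels below the highest such
replica (clamped at the ladder end). Each state then gets a dedicated
$s = 1$ run with bias offsets of +500 kJ/mol for itself and −500 kJ/mol for
the rest; the final configuration is accepted only if the state is the
maximal contributor throughout the last 30 % of the run (one retry at
doubled length). These runs also provide the physical-occurrence thresholds
$T_i^{phys}$ (0.95 quantile of the state's own energies while it is maximal
contributor). Finally, parallel energy-offset estimation (PEOE) runs a
12-replica ladder down to the lower bound and extracts, for every replica
meeting a stricter 0.9 occurrence criterion,
$E_i^{R} = -\beta^{-1}\ln\langle e^{-\beta(V_i - V_R)}\rangle_R$, averaging
the per-replica estimates.

The quantile threshold estimator, and the 0.95 default, are package
choices: the underlying workflow prescribes only that thresholds come from
these two runs. Quantiles are robust to single outliers and reproducible;
the quantile is exposed in `exploration_config()`. A second choice: when no
replica meets the strict 0.9 criterion (possible on short toy runs), the
orchestrator warns and falls back to the lowest-$s$ replica, rather than
aborting an unattended pipeline; the low-level `peoe_estimate()` keeps the
strict contract and errors.

**3. Optimization.** Ladder refinement alternates short runs with N-LRTO
insertions: exchange bottlenecks are scored per end state (severity = 1 −
acceptance over attempts where the state was maximal contributor on either
side; unattempted intervals count as severity 1), four replicas per
iteration are distributed round-robin over the per-state worst intervals,
linearly interpolated inside each interval, with all previous $s$-values
retained. Interpolation is linear in $s$, not $\log s$, even though the
initial ladder is logarithmic — the refinement targets a *local* gap, where
linear spacing is the defined behaviour. Iterations stop when every state
has nonzero maximal-contribution fraction at $s=1$, at least one round trip
occurred, and $\bar\tau / n_{RT} < 0.5$ ns-equivalent. The literal ratio is
used (mean round-trip time over round-trip count); a plausible alternative
reading — improvement of $\bar\tau$ per iteration — is not implemented, but
both quantities are kept in the iteration history so either can be
inspected. Times in MC steps are mapped to nanosecond-denominated criteria
through `steps_per_ns` (default $5\times10^5$, the 2 fs MD analogy).

With the ladder frozen, offset rebalancing iterates
$E_i \leftarrow E_i - \beta^{-1}\ln\!\big((f_i^{mc}+c)/(1/N+c)\big)$ with
pseudo count $c = (1/N)/x$ and intensity factor $x = 30$. The correction is
exactly zero at ideal sampling and capped at $\beta^{-1}\ln(x+1)$ (8.57
kJ/mol at 300 K) for a never-sampled state. The widely quoted cap of
8.43 kJ/mol corresponds instead to $k_BT\ln x$ at 298.15 K; both magnitudes
are exposed via `rebalance_correction_cap()` and reported side by side
rather than reconciled. Rebalancing stops when
$\max_i |f_i^{mc} - 1/N| \le 0.12$ (matching the observed post-rebalancing
deviation band; configurable) or after `max_rebalance_iterations`
(default 20). The cap default is deliberately generous: on the toy
benchmark the PEOE estimates can be tens of kJ/mol off (poor overlap, see
above), and with per-step corrections capped near 8.6 kJ/mol the fixed
point may need ~15 iterations. Round trips during rebalancing keep the
$s=1$ replica responsive to offset changes; the history records both.

**4. Production and analysis.** A replica-exchange run with frozen
parameters; the $s=1$ frames feed `zwanzig_multistate()`. Uncertainties are
first-order ("Gaussian") propagation of the blocked standard error of each
exponential average: with log-weights $a_t = -\beta(V_i - V_R)_t$, block
log-means are exponentiated relative to the global log-mean (all in log
space, so 500 kJ/mol gaps cannot overflow), their standard error is the
relative error of $\langle w\rangle$, and pair uncertainties add in
quadrature divided by $\beta$. Ten blocks by default; blocking absorbs
autocorrelation, and the estimator is validated against a nonparametric
bootstrap (agreement within 30 % on i.i.d. weights). The exact
Gaussian-error formula used by the reference implementation is not public;
this propagation is the package's documented interpretation. Environment
combination, reference statistics (RMSE with 100-fold bootstrap, MAE,
Spearman over all ordered pairs) and experimental anchoring
(`anchored_absolute()`, averaging over all anchor choices) complete the
analysis.

## Numerical choices

* All mixture arithmetic is max-shifted log-sum-exp; weights are computed
  in log space. $k_B = 0.00831446$ kJ/(mol K), $T = 300$ K by default.
* The propagator is Metropolis Monte Carlo with Gaussian proposals —
  exactly canonical at any proposal width, so acceptance-sensitive tests
  carry no discretisation bias. The default width matches the Boltzmann
  width of the toy wells, $\sqrt{k_BT/\bar k}$. An overdamped-Langevin
  integrator is available for MD-likeness but is not used by the pipeline.
* Exchange sweeps alternate even/odd neighbour pairs; accepted swaps
  exchange configurations while replica identities walk the ladder, and a
  round trip is one replica's top → bottom → top traversal.
* Argmin ties in the maximal-contributor metric go to the lowest state
  index — measure-zero for continuous systems, but tests need determinism.
* Degenerate inputs: empty trajectories, missing thresholds, non-finite
  energies and dimension mismatches raise errors naming the offending
  state or line; ladder refinement coalesces duplicate $s$-values within
  $10^{-12}$ relative.
* Exchanged quantity: configurations are swapped and replica identity
  tracked (the bookkeeping-equivalent alternative would swap $s$-values).

## Problem sizes

The shipped defaults are toy-scale: exploration 4000 steps/replica over 21
replicas, per-state optimization 2000 steps, PEOE 6000 steps over 12
replicas, ladder iterations on a 3000/6000/9000-step ramp (the
short-first-then-grow pattern of the reference protocol, in MC-step units),
rebalancing 3000 steps per iteration, production 40 000 steps/replica. A
full benchmark pipeline is a few times $10^6$ MC moves and recovers every
pairwise $\Delta G$ of the five-state benchmark within
$\max(0.3\ \text{kJ/mol},\ 3\sigma)$ of the closed forms; the acceptance
script reports the realised errors.

## Known limitations

* PEOE accuracy on toys with well-separated narrow minima is overlap
  limited (see above); the pipeline compensates through rebalancing, at the
  cost of more iterations than a molecular system would need.
* The global ladder re-distribution variant of round-trip optimization is
  not implemented — only the local (insertion-based) multistate variant.
* Thresholds are estimated once, during exploration, with the offsets then
  in force; later stages reuse them unchanged, which is faithful to the
  reference protocol but means undersampling diagnostics drift once offsets
  move far.
* Quadrature free-energy oracles are 1D only; multi-dimensional oracles
  exist only for harmonic states.
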