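---
title: "Markov-state kinetics from replica exchange trajectories"
author: "remdkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov-state kinetics from replica exchange trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remdkin)
```

## The problem

Temperature replica exchange molecular dynamics (REMD, also called
parallel tempering) runs $M$ copies of a system in parallel at
temperatures $T_1 < \dots < T_M$ and periodically attempts to swap the
temperatures of neighbouring copies with the Metropolis probability

$$ p_{\mathrm{acc}} = \min\!\left(1,\; e^{(\beta_i - \beta_j)(U_i - U_j)}\right),
\qquad \beta = \tfrac{1}{RT}, $$

which preserves detailed balance between the canonical ensembles. The
method yields two complementary views of the same data: *R-trajectories*
(one per replica, continuous in time, wandering across temperatures) and
*T-trajectories* (one per temperature, stitched from whichever replica
occupies that rung, and therefore discontinuous at every accepted
exchange). This package analyses both views for a small peptide whose
conformational kinetics can be described by a handful of metastable
states along a single reaction coordinate — the distance $d_{ee}$
between the terminal side-chain carbons of diphenylalanine is the
motivating example — and reproduces, on synthetic data with known truth,
the workflow used to show that an external electric field collapses a
three-state conformational network to a single extended state.

The analysis chain is: **demultiplex** (replay the exchange permutation),
**diagnose** (exchange acceptance, the equal-occupancy rule, Gaussianity
of the potential-energy marginals), **assign** conformational states by
the transition-based assignment (TBA) rule on $d_{ee}$, and **estimate**
the master-equation rate matrix by direct transition counting (DTC).

## The kinetic model

States $1,\dots,N$ obey the master equation
$\dot{\mathbf p}(t) = \mathbf K\,\mathbf p(t)$, where the off-diagonal
element $k_{nm} \ge 0$ is the transition rate $m \to n$ and the columns
of $\mathbf K$ sum to zero. The equilibrium populations $\mathbf p^0$
satisfy $\mathbf K \mathbf p^0 = 0$: they form the right eigenvector for
the eigenvalue $\lambda_1 = 0$, which `stationary_distribution()`
extracts (and verifies is unique — a disconnected network fails loudly
rather than being pseudo-inverted). The lag-$\Delta$ propagator is
$\mathbf P(\Delta) = e^{\mathbf K \Delta}$, column-stochastic and a
semigroup; `propagator()` evaluates it with a dense matrix exponential.

**DTC estimator.** Given labelled frames at spacing $\Delta t$, the rate
estimate is $\hat k_{nm} = N_{m\to n} / \tau_m$ — the number of
*committed* $m \to n$ transitions divided by the total dwell time in $m$.
`dtc()` is the fitting function and returns a classed model object with
`print`, `summary`, `coef`, `vcov`, `predict` (propagators and population
evolution), `simulate` and `plot` (the state network with populations and
rate-weighted arrows) methods. Errors come from block averaging: each
sequence is cut into $B$ contiguous blocks, the rates are re-estimated
per block, and the standard error of the block means is reported
(`block_errors()`).

**TBA.** Reaction-coordinate cores are detected from the pooled
$d_{ee}$ density (`detect_cores()`): peaks above a prominence threshold
(5% of the maximum density by default), each core extending while the
density stays above 60% of its peak, truncated at the inter-peak density
minimum so cores are disjoint. Frames inside a core take its label;
buffer frames inherit the most recently visited core *within the current
segment*, so a buffer excursion that returns to the same core commits no
transition. Leading buffer frames of a segment inherit the first core
subsequently visited (a `"drop"` alternative labels them `NA`).
Assignment is done on the continuous R-trajectories and carried to the
T-view by `project_replica_assignments()`; segment boundaries at accepted
exchanges block both inheritance and transition counting, respecting the
discontinuity of T-trajectories.

**R/T consistency.** Propagators along R-trajectories are, to a good
approximation, weighted geometric means of the per-temperature
propagators, with weights the fraction of time spent at each rung.
`check_geometric_mean_relation()` evaluates
$\mathrm{normalise}\big(\prod_t [\mathbf P^{(t)}]^{w_t}\big)$ elementwise
against the replica propagator and reports the maximum deviation; on the
packaged runs it is well below the 0.05 tolerance used in the tests.
Entries where some per-temperature propagator is zero are skipped and
reported, since the geometric mean is then ill-defined.

## The synthetic generator

No public trajectories exist for the motivating study, so the package
ships a generator (`simulate_remd()`) that emulates the *statistical*
structure the analysis relies on, not the molecular mechanics:

* a 12-rung ladder spanning 310.00–373.45 K (`ff_ladder()`), with a
  geometric-spacing utility for custom ladders;
* an $N$-state continuous-time Markov jump process per replica, with
  Arrhenius-scaled rates
  $k(T) = k_0\, e^{-E_a/R\,(1/T - 1/T_{\mathrm{ref}})}$, propagated by
  exact exponential dwell-time (Gillespie) sampling and snapped to the
  1 ps frame grid — this avoids the time-discretisation bias of
  $k\,\Delta t$ schemes;
* Gaussian $d_{ee}$ emissions per state;
* Gaussian potential energies per temperature, mean linear in $T$ and
  common width $\sigma = 50$ kcal/mol, with the slope solved at
  scenario-build time from the closed-form expected Metropolis
  acceptance so the mean neighbour acceptance is 20%
  (`calibrate_energy_slope()`);
* neighbour swap attempts every 1 ps with alternating even/odd pairing
  (the attempt interval is a convention, not a measured quantity, and is
  configurable);
* one root seed, with per-replica sub-streams derived by fixed offsets
  so changing the replica count does not reshuffle other replicas.

The packaged scenarios encode the study conditions. `zero_field` has
three states (compact/intermediate/extended at 5.0/8.9/11.0 Å, emission
sd 0.5 Å) with stationary populations 0.38/0.42/0.20 at 310 K; the 42%
intermediate population and the 8.9 Å extended distance are anchored to
the reported values, the others are free generator choices. All
activation energies are equal (2.0 kcal/mol), so the stationary
distribution is temperature-invariant and the rate estimate cumulated
over all R-trajectories targets the same populations as any single
temperature — by construction the two readings of "the" population
coincide here. `field_30` and `field_45` implement the field by
reweighting the network: a single dominant extended state (stationary
probability 0.995) at 8.9 Å and 10.0 Å respectively, rather than by
coupling a force. Nominal production lengths are 126/100/98 ns per
replica; analyses in the tests and the acceptance script use
$10^5$ frames (100 ns at 1 ps) or less per replica, which the error
analysis shows is ample for the packaged rates.

### The uncorrected-initialisation artifact

An external field can stabilise a low-energy conformational ensemble in
*some* replicas before a run is (re)initialised, distorting the
potential-energy marginals that the exchange criterion relies on. In
`artifact_mode` the affected replicas (default the first two) carry a
mixture of the unperturbed and the field-stabilised ensemble — a slow
two-state toggle (35% low-energy occupancy, 100 ps correlation time,
offset 300 kcal/mol below the unperturbed mean). Two consequences mirror
the real failure: the affected replicas' energy traces are bimodal, and
the Metropolis criterion traps them at the bottom of the ladder, so the
lowest-temperature marginals are bimodal too and the equal-occupancy
rule fails. `corrected_restart()` returns the scenario with all replicas
initialised in the stabilised ensemble; the offset then shifts every
replica equally, cancels out of the exchange criterion, and all marginals
are single Gaussians again.

`energy_distribution_check()` makes the call quantitatively: it fits 1-
versus 2-component Gaussian mixtures (BIC-selected, via **mclust**) and
flags a series as bimodal only when the 2-component model wins *and* the
means are at least 2 pooled standard deviations apart. Skewness and
excess kurtosis are reported but advisory. On pure Gaussians the false
flag rate is below 1%; equal-weight mixtures 6 sigma apart are always
caught (both are exercised in the tests, at 200 replicates of 2000
points and 20 replicates of 10<sup>4</sup> points respectively).
`energy_artifact_report()` applies the check per temperature (the
marginal each rung actually samples) or per replica; replica series mix
the twelve per-temperature Gaussians, so they are first centred by the
per-temperature median energy. The pipeline defaults to the
per-temperature view, which is the one that localises the artifact at
the bottom of the ladder.

## Diagnostics and thresholds

* **Acceptance**: `acceptance_rate()` reports the overall and per-pair
  accepted fraction; the packaged energy model is calibrated to 20%.
* **Equal occupancy**: a converged run has every replica spending
  $\approx 1/M$ of its time at each rung. The deviation statistic is
  $\max_{r,t} |\Omega_{rt} - 1/M|$ with a default pass threshold of
  $0.5/M$ — the rule itself is standard, the cutoff is a package choice
  and configurable.
* **Energy Gaussianity**: thresholds as above; there is no quantitative
  criterion in the motivating study (the artifact is shown graphically),
  so the BIC + 2-pooled-sigma rule is a package decision.

## Numerical choices and degenerate inputs

* Histogram modes use fixed 0.1 Å bins aligned to multiples of the bin
  width; ties resolve to the lowest bin centre. A constant series gets a
  single bin centred on its value.
* Core detection smooths the binned density with a 3-bin moving average
  before peak finding; peak prominence is topographic (height above the
  higher key saddle, measured to the boundary when no higher peak exists
  on a side).
* `stationary_distribution()` checks column sums, non-negativity of
  off-diagonal rates, and connectivity (components are named in the
  error); small negative eigenvector entries from roundoff are clipped
  and renormalised.
* Rate columns of states never visited are `NA` ("undetermined"), never
  silently zero; an all-zero count matrix yields $K = 0$ with a warning.
* Single-rung ladders are accepted as a degenerate case (plain
  constant-temperature dynamics; no exchange, and no acceptance
  calibration possible).
* superposition RMSD uses the SVD-based optimal rotation with the
  determinant correction against reflections.

## What passing tests do and do not show

The generator produces exactly the distributional structure the
estimators assume: Gaussian emissions, Markovian state dynamics,
Gaussian energy marginals, instantaneous uncorrelated energies at
attempt times. Real MD data violate all of these to some degree
(non-Gaussian coordinate distributions, non-Markovian memory at short
lags, autocorrelated energies), so green tests here validate the
*implementation* of the workflow and its internal consistency — they do
not certify the physical model for any particular peptide. Two known
limitations deserve note:

* **Discretisation bias of DTC.** With frames every $\Delta t$, jumps
  that occur within one frame interval collapse, biasing rates low by
  $O(k\,\Delta t)$ — about 1–3% at $k \approx 0.017\,\mathrm{ps}^{-1}$
  and 1 ps frames, which can exceed the statistical error of long runs.
  Stationary populations are essentially unaffected (the bias largely
  cancels in the detailed-balance ratios). The rate-recovery property
  test therefore uses rates $\le 0.006\,\mathrm{ps}^{-1}$, where
  statistical error dominates; a lag-scan of the empirical propagator is
  the standard Markovianity check when this matters.
* **Block-SEM stability.** With only 5 blocks the SEM is itself noisy
  (4 degrees of freedom); strict 3-SEM bands in the tests use 10 blocks.

## Problem sizes used by the test suite and acceptance script

The reference zero-field run is 12 replicas × 10<sup>5</sup> frames
(100 ns at 1 ps), generated once and reused; field scenarios use
~10<sup>5</sup> pooled frames; the exchange-acceptance estimate uses
~10<sup>5</sup> attempts; rate-recovery chains total 1.2–1.5 × 10<sup>6</sup>
frames. These sizes put every statistical tolerance used in the tests at
least a factor of a few above the corresponding sampling error.

## A worked example

```{r example, eval = FALSE}
report <- run_remd_pipeline("zero_field", n_frames = 1e5, seed = 1)
print(report)
summary(report$fit)
plot(report$fit)      # 3-state network, arrow width ~ rate
```

An uncorrected field run halts at the energy check; the corrected
restart goes through:

```{r artifact, eval = FALSE}
sc <- build_scenario("field_30", artifact_mode = TRUE)
try(run_remd_pipeline(sc, n_frames = 6000, seed = 1))
ok <- run_remd_pipeline(corrected_restart(sc), n_frames = 6000, seed = 1)
```
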