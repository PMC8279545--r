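# remdkin

Markov-state kinetics from temperature replica exchange molecular
dynamics (REMD) trajectories.

REMD runs M replicas of a solvated molecule in parallel at increasing
temperatures and periodically swaps neighbouring temperatures with the
Metropolis probability `min(1, exp((beta_i - beta_j)(U_i - U_j)))`. The
data come in two views: continuous per-replica *R-trajectories* and
discontinuous per-temperature *T-trajectories* (stitched at every
accepted exchange). For a small peptide whose conformations separate
along a single reaction coordinate — here the side-chain end-to-end
distance d_ee of diphenylalanine — the conformational kinetics can be
modelled by a master equation `dp/dt = K p`, with `k_nm` the m -> n
transition rate and the equilibrium populations `p0` given by the
eigenvector of K at eigenvalue 0.

The package implements the full workflow:

* **Synthetic REMD generator** (`simulate_remd`, `build_scenario`):
  Metropolis neighbour swaps over a 310.00–373.45 K 12-rung ladder
  driving an N-state Markov jump process with Arrhenius rates, Gaussian
  d_ee emissions, and a Gaussian per-temperature energy model calibrated
  analytically to a 20% average exchange acceptance. Packaged scenarios:
  `zero_field` (3 states, populations 0.38/0.42/0.20), `field_30` and
  `field_45` (one dominant extended state at 8.9 / 10.0 Å — the
  electric-field-collapsed network), plus an *artifact mode* emulating
  uncorrected initial conditions under a field.
* **Demultiplexing** (`demux` / `remux`): exact permutation replay
  between R- and T-views, plus exchange-log I/O.
* **Diagnostics**: exchange acceptance (`acceptance_rate`), the
  equal-occupancy rule (`occupancy`), and detection of field-induced
  non-Gaussian potential-energy distributions
  (`energy_distribution_check`, `energy_artifact_report`), with
  `corrected_restart` to re-initialise a distorted run.
* **Observables** (`end_to_end_distance`, `heavy_atom_rmsd`,
  `dipole_moment`, `obs_histogram`) over PDB/XYZ structures and
  columnar trajectory files.
* **Transition-based assignment** (`detect_cores`, `assign_tba`,
  `project_replica_assignments`): core/buffer state labelling on d_ee
  that commits a transition only when a different core is entered, and
  never inherits across T-trajectory discontinuities.
* **Direct transition counting** (`dtc`): `k_nm = N(m->n) / tau_m`, with
  stationary populations, block-averaged standard errors, propagators
  `exp(K * lag)` (`propagator`, `empirical_propagator`), the R/T
  weighted-geometric-mean propagator consistency check, and a kinetic
  network report. `dtc()` returns a model object with `print`,
  `summary`, `coef`, `vcov`, `predict`, `simulate` and `plot` methods.
* **Pipeline** (`run_remd_pipeline`): simulate/load -> diagnose ->
  assign -> estimate -> report, deterministic for a given seed, halting
  on failed diagnostics. A thin CLI lives in `inst/cli/remdkin`.

## Worked example

```r
library(remdkin)
report <- run_remd_pipeline("zero_field", n_frames = 2e4, seed = 1)
print(report)
```

```
REMD analysis report: scenario 'zero_field', seed 1, 20000 frames/replica
  exchange acceptance: 20.2%
  equal occupancy: pass (deviation 0.0315)
  energy check: pass
  3 state(s); populations: 38.3%, 41.8%, 19.9%
  d_ee histogram mode: 8.95 A
```

The run passes all three convergence diagnostics (acceptance near the
20% design value; every replica visits every temperature nearly
uniformly; all energy marginals unimodal), the d_ee density resolves
three conformational cores, and the estimated stationary populations
recover the generator truth (38/42/20%) to within sampling error.

```r
summary(report$fit)
```

```
DTC kinetic model: 3 state(s), 240000 frames, 5 error blocks
Transition rates (1/ps):
 from to counts      rate      se
    1  2   1423 1.551e-02 4.7e-04
    1  3      5 5.449e-05 2.4e-05
    2  1   1414 1.407e-02 4.8e-04
    2  3   1133 1.128e-02 2.2e-04
    3  1     17 3.558e-04 6.2e-05
    3  2   1122 2.349e-02 5.1e-04
Stationary populations: 38.3%, 41.8%, 19.9%
```

The compact <-> intermediate and intermediate <-> extended exchanges
dominate; direct compact <-> extended transitions are two orders of
magnitude rarer (those few counts are buffer-crossing events). Running
the same pipeline on `"field_30"` or `"field_45"` yields a single
populated state (> 99%) with the d_ee mode at 8.9 Å / 10.0 Å — the
field-collapsed network. `summary(build_scenario("zero_field"))` also
reports the scenario bookkeeping: 12 replicas x 126 ns = 1.512 us of
nominal production.

An uncorrected field run is caught by the energy diagnostic and refused:

```r
sc <- build_scenario("field_30", artifact_mode = TRUE)
run_remd_pipeline(sc, n_frames = 6000, seed = 1)
#> Error: pipeline stage 'energy_check' failed: non-Gaussian energy
#> distribution(s) flagged (temperature 1, 2, 4); correct the initial
#> conditions (corrected_restart) or rerun with force = TRUE
run_remd_pipeline(corrected_restart(sc), n_frames = 6000, seed = 1)  # passes
```

See `vignettes/remd-kinetics.Rmd` for the model, the generator's
assumptions, and the numerical choices.

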