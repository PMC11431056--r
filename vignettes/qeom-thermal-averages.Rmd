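---
title: "Reconstructing molecular thermal states with qEOM and informationally complete measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing molecular thermal states with qEOM and informationally complete measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeomtherm)
```

## The problem

Thermal averages of a molecule at inverse temperature $\beta$ are
expectations against the Gibbs state
$\rho_{\mathrm{th}} = \frac{1}{Z}\sum_n e^{-\beta E_n}\,|n\rangle\langle n|$.
At low temperature only the few lowest eigenpairs matter, so a workable
route on a (simulated) quantum register is: prepare the ground state
$|0\rangle$, obtain low-lying excitation energies and states from it, and
assemble the truncated Gibbs sum.  This package simulates that workflow
end to end for small complete-active-space (CAS) molecular Hamiltonians
and quantifies its accuracy against exact diagonalization.

The pipeline has four stages, each exposed as ordinary package functions:

1. **Hamiltonians** — FCIDUMP input or synthetic generators, second
   quantization over spin orbitals, Jordan–Wigner mapping to an $N$-qubit
   Pauli-string operator (`read_fcidump()`, `polyene_pi_integrals()`,
   `synthesize_integrals()`, `qubit_hamiltonian()`).
2. **Ground state** — exact particle-number-filtered diagonalization
   (`exact_eigenstates()`) or a noiseless UCCSD variational eigensolver
   (`vqe_optimize()`).
3. **Excited states** — the quantum equation-of-motion (qEOM) method:
   double-commutator matrix elements over an excitation-operator pool,
   estimated either exactly or from simulated SIC-POVM measurement
   outcomes, followed by a generalized eigenvalue problem
   (`build_eom_observables()`, `estimate_matrix_elements()`,
   `solve_gep()`, `reconstruct_excited_states()`).
4. **Thermal benchmarking** — Gibbs assembly, trace distance and
   thermal-energy error versus the exact sector Gibbs state
   (`thermal_state()`, `trace_distance()`, `thermal_energy()`,
   `run_experiment()`).

## The equation-of-motion step

For an excitation operator ansatz
$O_n^\dagger = \sum_\mu X_\mu E_\mu - Y_\mu E_\mu^\dagger$ built from a
pool $\{E_\mu\}$ of particle-number-conserving single and double
excitations, stationarity of the excitation-energy functional yields the
block generalized eigenvalue problem

$$
\begin{pmatrix} M & Q \\ Q^* & M^* \end{pmatrix}
\begin{pmatrix} X_n \\ Y_n \end{pmatrix}
= E_{0n}
\begin{pmatrix} V & W \\ -W^* & -V^* \end{pmatrix}
\begin{pmatrix} X_n \\ Y_n \end{pmatrix},
$$

with $M_{\mu\nu} = \langle 0|[E_\mu^\dagger, H, E_\nu]|0\rangle$ and
$Q_{\mu\nu} = -\langle 0|[E_\mu^\dagger, H, E_\nu^\dagger]|0\rangle$
using the symmetrized double commutator
$[A,B,C] = ([[A,B],C] + [A,[B,C]])/2$, and the single-commutator metric
blocks $V_{\mu\nu} = \langle 0|[E_\mu^\dagger, E_\nu]|0\rangle$,
$W_{\mu\nu} = -\langle 0|[E_\mu^\dagger, E_\nu^\dagger]|0\rangle$.

The pool contains **all** spin-orbital singles and doubles relative to
the Hartree–Fock reference, including spin-flip singles — 5 operators
for CAS(2,2) and 52 for CAS(4,4) — so the four matrices require
$4n^2$ expectation values (100 and 10,816).  This pool is deliberately
larger than the spin-preserving UCCSD amplitude set (3 and 26): the two
counting rules serve different objects (variational parameters versus
measured matrix elements) and both are exposed for inspection
(`uccsd_parameter_count()`, `$n_observables`).

### Numerical choices in the solver

* **Symmetry repair.**  Finite sampling breaks the exact symmetry of the
  estimated matrices; before solving, `solve_gep()` projects each block
  onto its exact symmetry class — $M, V$ Hermitian, $Q$ symmetric, $W$
  antisymmetric.  $Q$ and $W$ are repaired as well as $M$ and $V$ because
  each appears twice in the block pencil and an unsymmetrized estimate
  would make the two occurrences inconsistent.
* **Realness.**  With real orbital integrals and a real ground state —
  the only case this package produces — every matrix element is exactly
  real, so `estimate_matrix_elements(assume_real = TRUE)` discards the
  imaginary part of the estimates.  This is an unbiased variance
  reduction, not an approximation.
* **Metric regularization.**  The indefinite Hermitian metric is
  eigendecomposed and directions with $|\lambda|$ below
  `metric_tol` $\times$ the largest magnitude (default $10^{-8}$,
  logged as `metric_rank`) are discarded before the reduced
  non-Hermitian eigenproblem is solved.
* **Branch selection.**  The pencil spectrum is symmetric under
  $E \to -E$; solutions with real part above $10^{-10}$ and relative
  imaginary part below $10^{-6}$ are retained ascending, others are
  dropped with a conditioning flag on the result.
* **Ground-state projection and degenerate orthonormalization.**  The
  finite pool satisfies the vacuum-annihilation condition only
  approximately, so the raw candidates $O_n^\dagger|0\rangle$ carry a
  spurious ground-state component; `reconstruct_excited_states()`
  projects it out, and Gram–Schmidt-orthonormalizes members of
  near-degenerate energy groups (tolerance $10^{-8}$ Ha) inside their
  common eigenspace.  On two-electron systems with exact inputs this
  restores every reconstructed state to unit fidelity; without the
  repair the contamination is $O(10^{-1})$ in amplitude even though the
  excitation energies themselves are exact.

## Measurement simulation

Every matrix element is estimated from **one shared set** of simulated
measurement outcomes of the canonical symmetric informationally complete
POVM, whose four single-qubit effects $\Pi_i = |\psi_i\rangle\langle\psi_i|/2$
satisfy $\mathrm{Tr}[(2\Pi_i)(2\Pi_j)] = (2\delta_{ij}+1)/3$.  The dual
frame is closed form, $D_i = 3(2\Pi_i) - I$, and any observable
decomposes as $O = \sum_m \mathrm{Tr}[D_m O]\,\Pi_m$, giving the
unbiased estimator $\bar O = \frac1S \sum_s \omega_{m_s}$ with
per-outcome weights that factorize over qubits.

Internally the package never loops over the $4n^2$ observables times $S$
shots.  The empirical outcome-frequency tensor is mapped through the
per-qubit dual-overlap matrices, which yields the estimated expectation
of *every* Pauli string at once — equivalently the linear-inversion
reconstruction $\hat\rho = \sum_P \widehat{\langle P\rangle} P / 2^N$ —
and each matrix element is then the trace of $\hat\rho$ against the
commutator observable, evaluated with dense BLAS.  This is algebraically
identical to averaging the per-sample weights (it is tested as such),
and reduces the cost to one pass over the samples plus dense linear
algebra in the $2^N$-dimensional space.  Registers beyond 8 qubits are
sampled by sequential per-qubit conditioning instead of enumerating the
$4^N$ outcome table; dense realizations are capped at 12 qubits.

Per-element standard errors (`errors = "full"`) use the per-sample
route and are intended for small registers.

## Ground-state preparation

The UCCSD ansatz applies $e^{T - T^\dagger}$ to the Hartree–Fock
determinant as a single exact matrix exponential — no Trotter splitting,
so ansatz error never confounds the attribution of thermal-state error.
The optimizer is deterministic from zero initial amplitudes: BFGS with
finite-difference gradients, followed by a Nelder–Mead polish because
the gradient noise floor otherwise stalls convergence around $10^{-6}$
on badly scaled synthetic instances (amplitudes can be $O(10)$ when the
integrals are unscaled standard normals).  Convergence is on the energy
with relative tolerance $10^{-9}$.  No sampling noise enters the VQE:
measurement noise is confined to the EOM matrix estimation, so the
finite-shot curves isolate that single noise source.

In finite-sampling mode the ground-state energy $\langle H\rangle$ is
also estimated from the same sample set and recorded as a diagnostic
(`e0_estimate`).  It does not enter the reported metrics: Gibbs weights
depend only on energy *differences*, and the reconstructed ensemble's
energy is evaluated as $\mathrm{Tr}[\rho H]$.

## The synthetic systems

No ab initio integrals ship with the package; instead two kinds of
synthetic active spaces are generated in code:

* `synthesize_integrals()` draws random integrals with the correct
  one- and two-electron permutation symmetries — structureless test
  systems for the algebraic invariants (e.g. the two-electron exactness
  property of qEOM).
* `polyene_pi_integrals()` builds the standard Pariser–Parr–Pople
  $\pi$-electron model of a linear polyene: alternating double/single
  Hückel hoppings $t = -2.58 / -2.22$ eV on $1.35/1.46$ Å bonds,
  on-site $U = 11.26$ eV, Ohno long-range repulsion
  $V(r) = U/\sqrt{1 + (Ur/e^2)^2}$, and the conventional
  charge-neutralizing shifts.  The table is rotated to the Hückel
  molecular-orbital basis, where the closed-shell reference determinant
  is meaningful (in the site basis every site is half filled and the
  EOM metric vanishes identically).  `n_sites = 2` is an ethylene-like
  CAS(2,2) (4 qubits), `n_sites = 4` a butadiene-like CAS(4,4)
  (8 qubits) with a singlet–triplet gap of $\approx 2.7$ eV and an
  optical gap of $\approx 5.4$ eV — realistic polyene scales.  Copies
  are shipped as plain-text FCIDUMP fixtures with `synthetic` in their
  names, and regenerating them from code reproduces the files exactly.

What these models do *not* emulate: ab initio orbital shapes and
dynamic correlation from outside the active space, point-group
symmetry labels, and the precise spectra of the real molecules.
Passing tests therefore demonstrate the *method* — exactness limits,
estimator calibration, shot-budget scaling — on systems of the right
size and energy scale, not spectroscopic agreement with experiment.

## Experiment design and problem sizes

`run_experiment()` crosses ground-state mode × shot budget ×
repetition, reusing one sample set per repetition for all observables,
and scores every $\beta$ against the exact particle-number-sector Gibbs
state (both embedded in the full $2^N$ space).  Repetition seeds are
derived from the master seed by a counter and recorded per row, so runs
are reproducible from the configuration alone.  `summarize_runs()`
reports medians with central 99.7-percentile intervals as order
statistics, the spread convention used throughout.

Default conditions follow the study design: shot budgets
$\{10^4, 10^5, 10^6\}$, 100 repetitions, $\beta \in [0, 100]$ Ha$^{-1}$.
The package's own test suite scales repetitions down to 10 and uses the
CAS(2,2)/CAS(4,4) fixtures, sizes chosen so the full suite completes in
a few minutes on one core; the method's behaviour (shot-budget
ordering, chemical-precision region at large $\beta$) is already
resolved at those sizes.

A worked example:

```{r example, eval = FALSE}
tab <- polyene_pi_integrals(4)
cfg <- qeom_config(tab, gs_mode = "exact", sampling = "finite",
                   shots = c(1e4, 1e5), beta = c(1, 5, 10, 20, 40, 100),
                   repetitions = 10, seed = 1)
runs <- run_experiment(cfg)
summarize_runs(runs)
autoplot(runs, metric = "delta_e")
```

## Known limitations

* Dense statevector simulation limits registers to 12 qubits, and the
  shared-sample estimator to 8 (beyond that the per-sample weight route
  still works but is slow).
* The excitation pool stops at doubles; at high temperature the
  truncated spectrum cannot represent the full sector Gibbs state, and
  the trace distance saturates accordingly (visible below
  $\beta \approx 40$ for the CAS(4,4) fixture).
* Eigenvalue noise from finite sampling biases the lowest retained
  excitation energies downward (an ordering effect), which is the
  dominant contribution to the thermal-energy error near the
  chemical-precision boundary at $\beta \approx 40$.
* Spin symmetry is not exploited: no spin-adapted blocking of the EOM
  matrices and no purification of reconstructed states.
* Measurement noise models (detector tomography) and adaptive POVM
  optimization are out of scope; the POVM is the fixed canonical SIC.
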