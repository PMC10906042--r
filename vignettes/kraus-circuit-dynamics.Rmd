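---
title: "Exact non-Markovian dynamics as Kraus-operator circuits: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact non-Markovian dynamics as Kraus-operator circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(krausdyn)
```

## The problem

A small quantum system (a tunneling two-level system, a handful of coupled
chromophore sites) exchanging energy with a macroscopic vibrational
environment does not evolve unitarily, and at finite temperature with a
structured environment it does not evolve under a Lindblad semigroup either:
the bath retains memory of the system's past.  `krausdyn` computes the exact
reduced dynamics of such systems — within a controlled discretization — and
re-expresses it in a form a gate-based quantum computer can execute: a small
set of Kraus operators, each compiled into a shallow postselection circuit.

The pipeline has four stages, each a module of the package:

1. **bath / pathint** — influence-functional path integral: build the exact
   linear map (superpropagator) `T(t)` carrying `vec(rho(0))` to
   `vec(rho(t))`.
2. **kraus_algebra** — convert `T(t)` to an operator sum
   `rho -> sum_k M_k rho M_k^dag` through the Choi matrix.
3. **circuits** — unitarize every `M_k` by SVD, dilate the singular-value
   diagonal with one ancilla, and synthesize the diagonal as a Walsh series
   of Pauli-Z-string rotations with Gray-code ordering.
4. **simulate** — execute the circuits on a statevector simulator (exactly
   or with shot sampling) and assemble populations by the operator-sum rule.

## Model and assumptions

The system (dimension `d`) couples bilinearly to one or more independent
harmonic baths.  Each bath's coupling operator is diagonal in the
propagation basis, with eigenvalues `coupling_values` (for a two-level
system coupled through sigma_z these are +1 and -1; for site-local baths of
an exciton model, the occupation indicator of the site).  The initial state
factorizes into the system state and thermal baths.  Everything the baths do
to the system is encoded in the finite-temperature response function

    alpha(t) = (1/pi) Int_0^inf J(w) [coth(beta w / 2) cos wt - i sin wt] dw

with the spectral density `J(w)` in one of two continuum families —
Ohmic with exponential cutoff, `J = (pi/2) xi w exp(-w/w_c)`, and Drude,
`J = 2 lambda gamma w / (w^2 + gamma^2)` — or as an explicit finite set of
modes (the `discrete` family, used for validation against exact
finite-bath reference models).  Prefactor conventions for `J` and `alpha`
differ across the literature; the adopted convention is exposed as an
advanced `prefactor` override on `bath_spec()` and, more importantly, is
*validated* rather than assumed: a two-mode discretization of the Ohmic
density, propagated exactly as system ⊗ truncated oscillators, agrees with
the path-integral engine to a few 1e-3 (see the test suite).  That check
ties together the `J` convention, the microscopic mode couplings, the form
of `alpha`, and the sign of the influence functional in a single loop — if
any one of them were inconsistent, the two propagations would disagree at
leading order.

Internal units set `hbar = k_B = 1`.  Dimensionless spin-boson parameters
are used as given; wavenumber-parameterized models are converted by
`convert_units()` (cm^-1 to rad/fs via `2 pi c`, kelvin to inverse energy),
so time is in fs for such models.

## Discretized influence functional

The path integral is discretized on a grid `t_k = k dt`.  Each path point
owns a time window: interior points the centered window
`[t_k - dt/2, t_k + dt/2]`, the two end points half windows, so the windows
tile `[0, t_n]` exactly.  The influence coefficients are genuine double
integrals of `alpha` over window pairs (`eta_table()`), evaluated as single
frequency-space quadratures with analytically integrated window kernels —
numerically stable at `w -> 0` through series expansions of
`w coth(beta w/2)` and the window sinc factors.  Interior-pair coefficients
depend only on the separation `k - k'` (stationarity); coefficients
involving an end point form separate classes, and the map read-out at every
intermediate `t_n` converts the newest point's coefficients from interior
to terminal classes on the fly.  This windowing makes the discretization
second-order accurate in `dt`: the `n = 1` classes alone reproduce the
exact time-ordered double integral of `alpha` over the first step.

For the Drude family the response function itself decays too slowly in
frequency for a truncated quadrature, so `bath_response()` adds the
analytic high-frequency tail through cosine/sine integrals.  (At exactly
`t = 0` the Drude `Re alpha` is logarithmically divergent — a property of
the model, not a numerical defect; all window-integrated coefficients are
finite.)

## Tensor-network propagation and its truncation

Summing over all path pairs costs `d^(2(n+1))` and is kept only as the
`brute_force_map()` oracle (guarded to tiny problems).  The production
engine propagates the augmented path tensor as a matrix-product state with
one site per path variable inside the memory window `dk_max`, plus a
permanent site carrying the free initial index of the map, so a single
propagation yields the full `d^2 x d^2` superpropagator at every time
point.  Each step applies the new variable's pair factors as a
front-conditioned diagonal MPO (zip-up with immediate truncation),
variables older than `dk_max` are summed out, and an
orthogonalization + truncation sweep keeps bonds tight.

Numerical choices:

* **`svd_cutoff` (default 1e-10)** — relative singular-value threshold for
  bond truncation.  This is the only approximation besides `dt` and
  `dk_max`; with the default it sits far below the dynamics tolerances
  (the engine reproduces brute-force enumeration to ~1e-14 on small
  problems).
* **`chi_max` (default unbounded)** — a hard bond cap exists but is
  discouraged: unlike the relative cutoff, a hard cap can discard weight
  unevenly and has been observed to break complete positivity of the
  resulting map badly.  Prefer loosening `svd_cutoff`.
* **`dk_max`** — memory length in steps.  The bath response decays on a
  timescale set by the cutoff (and by `2 pi / beta` thermally); `dk_max`
  should cover it.  The CLI `converge` subcommand re-runs at halved `dt`
  and doubled memory and reports the population change.
* **`dt`** — the discretization is second order.  For the spin-boson
  demonstration parameters, `dt = 0.25` is accurate to about 2e-3 in
  populations and `dt = 0.125` to a few 1e-4 (the convergence test in the
  suite asserts the 1e-3 level from `dt = 0.125` downward).
* Maps are full-interval maps `0 -> t_n`; nothing is composed step-wise,
  which would silently assume Markovianity.
* After read-out the map is symmetrized to exactly preserve Hermiticity of
  its outputs; trace preservation is inherited from the discretization
  (the influence factors are unity on the diagonal of the final point) and
  holds to ~1e-12.

Problem sizes used in the shipped tests and in `scripts/acceptance.R` are
deliberately modest — spin-boson trajectories of 40 steps with `dk_max = 8`,
four-site runs of 5–10 steps with `dk_max = 2` to 3 — chosen so that the
whole suite re-runs quickly on a single CPU with reference BLAS while still
exercising every code path (full-rank d = 4 Choi spectra are already
obtained at these sizes).  Longer memories and finer grids are a matter of
budget, not of code path.

## From the map to Kraus operators

`choi_from_map()` applies the index reshuffle (involution)
`C[(i,j),(i',j')] = T[(i,i'),(j,j')]` in the column-stacking convention
(`vec(A X B) = (t(B) ⊗ A) vec(X)`); the convention is pinned by the
round-trip contract, tested for `d = 2, 3, 4`.  For a physical map the
Choi matrix is Hermitian and positive with trace `d`;
`kraus_from_choi()` eigendecomposes it and forms
`M_k = sqrt(lambda_k) unvec(u_k)`.

* **CPTP repair (budget 1e-6)** — tensor truncation leaves tiny negative
  Choi eigenvalues; they are clamped to zero and the spectrum rescaled to
  preserve the trace.  Violations beyond the budget abort with the
  measured floor: that is a convergence failure, not noise.
* **Drop floor (default 1e-9, relative)** — eigenvalues below the floor
  are dropped; a full-rank `d = 4` map keeps all 16 operators, the hard
  upper bound `d^2`.
* **Determinism** — operators are ordered by descending weight and each is
  phase-fixed by making its largest-magnitude entry real positive, so
  repeated runs are identical.  Along a trajectory,
  `align_kraus_trajectory()` additionally re-anchors phases to the
  previous time point by maximal overlap; eigenvector phases (and mixing
  within near-degenerate weight crossings) are gauge, so per-operator
  curves can jump while every k-summed observable is invariant — do not
  over-interpret individual operator trajectories.
* **Significance counting** — `count_significant()` reports how many
  operators exceed a relative weight threshold (default 1%).  For the
  spin-boson demonstration two operators dominate the weight, but the
  count at a small threshold is sensitive to the threshold itself and to
  the model conventions (the factor conventions of the tunneling term and
  the coupling eigenvalues), since the subleading weights sit near the
  percent scale.  Treat the dominant-operator count as a qualitative
  diagnostic, not a sharp observable.

## Circuits

Every Kraus operator of a trace-preserving map is a contraction, so its
SVD `M = U S V^dag` has singular values in `[0, 1]` and only the diagonal
`S` is nonunitary.  One ancilla suffices to dilate it: with phases
`phi_j = acos(sigma_j)` (principal branch) placed as `+phi` on the
ancilla-0 branch and `-phi` on the ancilla-1 branch, conjugation by a
Hadamard on the ancilla puts `diag(sigma)` in the ancilla 0 -> 0 block.
The sign of the off-diagonal dilation block is unobservable after
postselection and fixed to `+` for determinism.

The diagonal phase unitary is synthesized exactly as a Walsh series: the
phase vector `f` transforms to coefficients `a_j` (the transform is an
involution up to `2^-n`), each nonzero `a_j` becomes one Z-string rotation
`exp(i a_j Q_j)`, and Gray-code ordering of the strings cancels adjacent
parity CNOTs — the full series on `n` qubits costs `2^n - 2` CNOTs on
all-to-all connectivity, and the `a_0` term is a tracked global phase, not
a gate.  The dilation phase vector has an ancilla-odd symmetry that zeroes
half the coefficients (threshold `drop_tol`, default 1e-12 — exactness
first; the savings here come from structurally zero coefficients).  For
one system qubit the resulting dilated-diagonal circuit has depth 4 with
2 CNOTs, and the complete postselection circuit (native RZ/SX
decompositions of `U` and `V^dag`, two Hadamards, the dilated diagonal)
contains exactly those 2 CNOTs.  Multi-qubit `U`/`V` factors are applied
as opaque unitaries by the simulator and flagged in `circuit_metrics()`;
their native-gate compilation — and any device-topology routing — is out
of scope, so reported metrics are all-to-all metrics.

Because the native RZ/SX/CNOT set cannot realize an arbitrary determinant
phase, `circuit_ir` carries a tracked global phase; the composed-unitary
contract (`ancilla-0 block equals M`, tested to 1e-10) is exact, while
measurement statistics never see the phase.

## Execution and statistics

`run_circuit()` is a dense statevector simulator (cap: 12 qubits) with a
multinomial shot sampler; a seed fixes every sample.  For a pure initial
system state `|psi>`, the joint probability of (ancilla = 0, system = i)
in the circuit of `M_k` is exactly `|<i| M_k |psi>|^2` — *unrenormalized*
postselection, so summing the joint frequencies over `k` reconstructs the
populations of `rho(t)` directly; mixed initial states are handled by
eigendecomposing `rho(0)` and weighting one circuit family per
eigencomponent.  One circuit is built per (Kraus operator, eigencomponent,
time point): the map, and hence its operators, is time-point specific, so
no circuit is reused across times.  Outcome labels are bitstrings with
qubit 1 (the ancilla) leftmost; this labeling convention is stated here
and in `run_circuit()` rather than inherited from any compiler default.
In exact mode the circuit-assembled populations must agree with the direct
superoperator reference to 1e-6 (they agree to ~1e-15); in shots mode the
per-cell deviation obeys binomial statistics, tested with 4-sigma bounds.

## What the fixture generator does and does not emulate

`generate_fixtures()` produces, deterministically from one seed: full-rank
random CPTP maps for `d = 2, 3, 4` (Ginibre Kraus sets normalized so that
`sum M^dag M = I` holds to machine precision), random contractions, random
phase vectors, and a miniature spin-boson configuration.  These exercise
the algebra and circuit layers over a much broader class of channels than
the physical pipeline produces.  They do *not* emulate the structure of
path-integral maps (smooth time dependence, near-degenerate weight
crossings, small CP-repair noise), so passing the fixture-based tests says
nothing about discretization convergence — that is what the brute-force,
discretized-bath and dt-halving oracles are for.  Conversely, none of the
oracles probes strong-coupling regimes where the memory window or bond
dimension would need to grow substantially; claims there should be backed
by explicit `converge` runs.

## Known limitations

* Spectral densities: the two continuum families plus explicit discrete
  modes; no sub/super-Ohmic exponents, structured peaks, or
  time-dependent baths.
* Time-independent system Hamiltonians only.
* Circuit metrics assume all-to-all connectivity; no routing, no
  two-qubit-unitary (KAK) decomposition, no device noise.
* The statevector simulator is dense; 12 qubits is a practical cap.
* Reference BLAS makes large-bond complex SVDs the wall-clock bottleneck
  for `d = 4` with long memories; scale `dk_max`/`dt` accordingly or link
  an optimized BLAS.
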