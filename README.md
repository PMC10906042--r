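# krausdyn

Exact finite-temperature, non-Markovian open-quantum-system dynamics,
compiled into shallow quantum circuits.

`krausdyn` is for theoretical chemists and quantum-simulation researchers
who need the *exact* reduced dynamics of a small system — a tunneling
two-level system, a few coupled chromophore sites — embedded in a harmonic
environment with memory, and who want that dynamics in a form a gate-based
quantum computer (or its simulator) can run.

## The method

The reduced dynamics of a system linearly coupled to harmonic baths is
generated by the Feynman–Vernon influence functional: the bath enters only
through its spectral density J(ω) and the finite-temperature response

    α(t) = (1/π) ∫₀^∞ J(ω) [coth(βω/2) cos ωt − i sin ωt] dω,

whose time-nonlocality is the memory.  `krausdyn`:

1. discretizes the influence functional (window-integrated coefficients
   η_kk′ of α) and propagates the augmented path tensor as a
   matrix-product state over the memory window, yielding the exact
   superpropagator **T**(t): vec ρ(0) → vec ρ(t) at every grid point
   (`propagate_map()`, with a brute-force path-enumeration oracle
   `brute_force_map()`);
2. reshuffles **T**(t) into its Choi matrix and eigendecomposes it into at
   most d² Kraus operators, ρ(t) = Σₖ M_k ρ(0) M_k†
   (`choi_from_map()`, `kraus_from_choi()`);
3. unitarizes each M_k = U Σ V† by SVD, dilates the nonunitary diagonal
   Σ with a single ancilla (phases ± arccos σ_j conjugated by ancilla
   Hadamards), and synthesizes the diagonal unitary exactly as a
   Gray-code-ordered Walsh series of Pauli-Z-string rotations — 2ⁿ − 2
   CNOTs at most for n qubits (`build_kraus_circuit()`,
   `synthesize_diagonal()`);
4. executes the circuits on a built-in statevector simulator, exactly or
   with seeded shot sampling, and assembles populations from the
   unrenormalized ancilla-0 statistics (`population_dynamics()`).

Two model builders ship with the package: the spin-boson model with an
Ohmic bath (`build_spin_boson()`) and a 4-site Frenkel–Holstein exciton
model with site-local Drude baths (`build_fmo4()`; a clearly labelled
*synthetic* stand-in Hamiltonian is included, with a template for user
values).

## Worked example

```r
library(krausdyn)

sys  <- build_spin_boson(omega = 1, epsilon = 0, xi = 0.1,
                         omega_c = 7.5, beta = 5)
set  <- propagation_settings(dt = 0.25, n_steps = 6, dk_max = 6,
                             svd_cutoff = 1e-12)
maps <- propagate_map(sys, set)

kset <- kraus_from_choi(choi_from_map(maps[[7]]))   # map at t = 1.5
kset
#> <kraus_set> d = 2 with 4 operators
#>   weights: 1.468, 0.4583, 0.04858, 0.025
#>   tp_deficit: 1.45e-14  cp_floor: 0.025

build_kraus_circuit(kset$operators[[1]])
#> <circuit_ir> 2 qubits, 17 gates (depth 13 , 2 CNOT)

tt <- population_dynamics(sys, set, run_settings("exact"), maps = maps)
subset(as.data.frame(tt), state == 1)
#>    time state population reference
#> 1  0.00     1     1.0000    1.0000
#> 3  0.25     1     0.9388    0.9388
#> 5  0.50     1     0.7870    0.7870
#> 7  0.75     1     0.5906    0.5906
#> 9  1.00     1     0.3960    0.3960
#> 11 1.25     1     0.2425    0.2425
#> 13 1.50     1     0.1564    0.1564
```

The four weights are the Choi eigenvalues (they sum to d = 2; two
operators dominate), `tp_deficit` certifies Σ M†M = I to machine
precision, and the `population` column — assembled from the circuit
ensemble — matches the direct superoperator `reference` exactly in exact
mode.  `run_settings("shots", 20000, seed = 1)` switches to sampled
statistics.  A command-line front end (`exec/krausdyn`) exposes the same
pipeline as `map`, `kraus`, `circuits`, `run`, `metrics`, `fixtures` and
`converge` subcommands over JSON configs.

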