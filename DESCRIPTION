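Package: krausdyn
Title: Kraus-Operator Quantum Circuits for Exact Non-Markovian Open-System Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates exact finite-temperature non-Markovian dynamics of small
    open quantum systems as quantum circuits.  Influence-functional path-integral
    superpropagators are generated by a tensor-network (matrix-product-state)
    propagation of the discretized Feynman-Vernon influence functional, converted
    to Kraus operators through the Choi matrix, unitarized by singular value
    decomposition with an ancilla dilation of the singular-value diagonal, and
    synthesized into shallow circuits with Gray-code-ordered Walsh-series
    rotations.  A built-in statevector simulator executes the circuits exactly or
    with shot sampling.  Ships spin-boson and four-site exciton-transfer
    (Fenna-Matthews-Olson type) model builders with Ohmic and Drude baths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
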