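Package: qeomtherm
Title: Molecular Thermal Averages via the Quantum Equation of Motion with
    Informationally Complete Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a hybrid quantum-classical workflow for reconstructing
    low-temperature thermal (Gibbs) states of small molecular active spaces.
    Active-space Hamiltonians (FCIDUMP input or synthetic generators) are
    mapped to qubits with the Jordan-Wigner transformation; the ground state
    is prepared exactly or with a noiseless UCCSD variational quantum
    eigensolver; excitation energies are obtained from the quantum
    equation-of-motion (qEOM) generalized eigenvalue problem, whose matrix
    elements are estimated from simulated symmetric informationally complete
    POVM (SIC-POVM) measurement outcomes through dual-frame weights, reusing
    one shared sample set for every observable.  Reconstructed Gibbs states
    are benchmarked against exact particle-number-sector diagonalization with
    trace distance and thermal-energy error across shot budgets and inverse
    temperatures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    optparse,
    withr
Config/testthat/edition: 3
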