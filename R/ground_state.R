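#' Exact eigenstates filtered by particle number
#'
#' Dense diagonalization of a qubit Hamiltonian, retaining eigenvectors that
#' live in a fixed particle-number sector.  Because the Hamiltonian commutes
#' with the total number operator, the sector restriction is performed
#' exactly by diagonalizing the Hamiltonian block on the occupation-basis
#' states with the requested particle number, which also keeps degenerate
#' eigenspaces inside the sector.  States are orthonormal, ordered by
#' ascending energy with a deterministic tie-break (index of the
#' largest-magnitude amplitude), and phase-fixed so that the
#' largest-magnitude amplitude is real positive.
#'
#' @param H Hermitian [pauli_sum()] on at most 12 qubits.
#' @param n_particles integer sector label, or `NULL` for the full spectrum.
#' @return an object of class `spectrum_sector` with fields `energies`,
#'   `states` (columns), `n_particles`.
#' @export
exact_eigenstates <- function(H, n_particles = NULL) {
  if (!pauli_is_hermitian(H)) stop_arg("H must be Hermitian")
  check_dense_cap(H$n_qubits)
  d <- 2^H$n_qubits
  idx <- if (is.null(n_particles)) seq_len(d)
         else which(popcount(0:(d - 1L)) == n_particles)
  if (!length(idx)) stop_arg("empty particle-number sector")
  Hd <- pauli_dense(H)[idx, idx, drop = FALSE]
  e <- eigen((Hd + Conj(t(Hd))) / 2, symmetric = TRUE)
  states <- matrix(0 + 0i, d, length(idx))
  states[idx, ] <- e$vectors
  o <- order_with_tiebreak(e$values, states)
  energies <- e$values[o]
  states <- states[, o, drop = FALSE]
  for (k in seq_len(ncol(states))) {
    j <- which.max(abs(states[, k]))
    ph <- states[j, k] / abs(states[j, k])
    states[, k] <- states[, k] / ph
  }
  structure(list(energies = energies, states = states,
                 n_particles = n_particles),
            class = "spectrum_sector")
}

order_with_tiebreak <- function(values, states) {
  key <- vapply(seq_len(ncol(states)),
                function(k) which.max(abs(states[, k])), integer(1))
  order(values, key)
}

#' @export
print.spectrum_sector <- function(x, ...) {
  cat(sprintf("<spectrum_sector: %d states%s>\n", length(x$energies),
              if (is.null(x$n_particles)) ""
              else sprintf(", N = %d", x$n_particles)))
  cat("  energies:", format(utils::head(x$energies, 8), digits = 8), "\n")
  invisible(x)
}

#' UCCSD amplitude count
#'
#' Number of independent variational amplitudes of the spin-preserving
#' unitary coupled-cluster singles-and-doubles ansatz on a closed-shell
#' reference: occupied-to-virtual singles within each spin channel plus
#' distinct same-spin (aa, bb) and opposite-spin (ab) double excitations.
#'
#' @param n_electrons even electron count.
#' @param n_spatial_orbitals active spatial orbitals.
#' @export
uccsd_parameter_count <- function(n_electrons, n_spatial_orbitals) {
  length(uccsd_excitations(n_electrons, n_spatial_orbitals))
}

# spin-preserving cluster excitations as fermion_op term strings (0-based
# spin orbitals, block spin ordering); the parameter order is fixed here
uccsd_excitations <- function(n_electrons, n_spatial_orbitals) {
  if (n_electrons %% 2L != 0L)
    stop_arg("only closed-shell references are supported (even n_electrons)")
  n <- n_spatial_orbitals
  nocc <- n_electrons / 2L
  if (n_electrons > 2L * n) stop_arg("too many electrons for the active space")
  occ <- seq_len(nocc) - 1L
  virt <- setdiff(seq_len(n) - 1L, occ)
  terms <- character(0)
  if (!length(occ) || !length(virt)) return(terms)
  spin <- c(alpha = 0L, beta = n)
  # singles, per spin channel
  for (s in spin) for (i in occ) for (a in virt)
    terms <- c(terms, sprintf("%d^ %d", a + s, i + s))
  # same-spin doubles
  for (s in spin)
    if (length(occ) >= 2L && length(virt) >= 2L)
      for (i2 in seq_along(occ)) for (j2 in seq_len(i2 - 1L))
        for (a2 in seq_along(virt)) for (b2 in seq_len(a2 - 1L))
          terms <- c(terms, sprintf("%d^ %d^ %d %d",
                                    virt[a2] + s, virt[b2] + s,
                                    occ[j2] + s, occ[i2] + s))
  # opposite-spin doubles
  for (i in occ) for (a in virt) for (j in occ) for (b in virt)
    terms <- c(terms, sprintf("%d^ %d^ %d %d",
                              a + spin["alpha"], b + spin["beta"],
                              j + spin["beta"], i + spin["alpha"]))
  terms
}

# dense anti-Hermitian generators T_k - T_k^ for each amplitude
uccsd_generators <- function(integrals) {
  nm <- n_spin_orbitals(integrals)
  terms <- uccsd_excitations(integrals$n_electrons,
                             integrals$n_spatial_orbitals)
  lapply(terms, function(t) {
    fop <- fermion_op(t)
    pauli_dense(jordan_wigner(fop - fermion_dagger(fop), nm))
  })
}

#' Hartree-Fock reference determinant as a state vector
#' @inheritParams build_fermionic_hamiltonian
#' @export
reference_state <- function(integrals) {
  nm <- n_spin_orbitals(integrals)
  psi <- complex(2^nm)
  psi[sum(2^reference_occupations(integrals)) + 1L] <- 1 + 0i
  psi
}

# e^G psi for anti-Hermitian dense G, via eigendecomposition of iG
expm_apply_antiherm <- function(G, psi) {
  e <- eigen(1i * G, symmetric = TRUE)
  e$vectors %*% (exp(-1i * e$values) * (Conj(t(e$vectors)) %*% psi))
}

#' Prepare a UCCSD ansatz state (noiseless statevector)
#'
#' Applies `exp(T - T^dagger)` to the Hartree-Fock determinant as a single
#' exact matrix exponential of the anti-Hermitian cluster generator (no
#' Trotter splitting), where `T` is the spin-preserving singles+doubles
#' cluster operator with the given amplitudes.
#'
#' @inheritParams build_fermionic_hamiltonian
#' @param parameters amplitude vector, ordered as enumerated by
#'   [uccsd_parameter_count()] (singles by spin channel, then aa/bb, then
#'   ab doubles).
#' @return an object of class `ansatz_state` with fields `parameters`,
#'   `state`, `energy` (Hartree).
#' @export
prepare_uccsd_state <- function(integrals, parameters) {
  gens <- uccsd_generators(integrals)
  if (length(parameters) != length(gens))
    stop_arg("expected ", length(gens), " parameters, got ", length(parameters))
  H <- qubit_hamiltonian(integrals)
  state <- uccsd_state_fast(gens, parameters, reference_state(integrals))
  new_ansatz_state(parameters, state, H)
}

uccsd_state_fast <- function(gens, parameters, psi0) {
  d <- length(psi0)
  G <- matrix(0 + 0i, d, d)
  for (k in seq_along(gens)) if (parameters[k] != 0)
    G <- G + parameters[k] * gens[[k]]
  if (all(G == 0)) return(psi0)
  drop(expm_apply_antiherm(G, psi0))
}

new_ansatz_state <- function(parameters, state, H, converged = TRUE,
                             message = NULL) {
  energy <- Re(pauli_expect(H, state))
  structure(list(parameters = as.numeric(parameters), state = state,
                 energy = energy, converged = converged,
                 message = message),
            class = "ansatz_state")
}

#' @export
print.ansatz_state <- function(x, ...) {
  cat(sprintf("<ansatz_state: %d parameters, energy %.10f Ha%s>\n",
              length(x$parameters), x$energy,
              if (isTRUE(x$converged)) "" else " [not converged]"))
  invisible(x)
}

#' Variational ground-state optimization (noiseless UCCSD-VQE)
#'
#' Minimizes the exact (infinite-shot) Rayleigh quotient of the active-space
#' Hamiltonian over the UCCSD amplitudes with deterministic BFGS from zero
#' initial amplitudes (finite-difference gradients).  Measurement noise never
#' enters the optimization; sampling noise in this workflow is confined to
#' the equation-of-motion matrix estimation.
#'
#' @inheritParams prepare_uccsd_state
#' @param seed retained for interface symmetry; the zero-initialized
#'   deterministic optimizer does not consume randomness.
#' @param tol relative energy convergence tolerance.
#' @param maxit iteration cap; non-convergence is reported as a warning
#'   status on the result, not an error.
#' @return an `ansatz_state`; `converged` is `FALSE` if the iteration cap
#'   was hit.
#' @export
vqe_optimize <- function(integrals, seed = 1L, tol = 1e-9, maxit = 500L) {
  gens <- uccsd_generators(integrals)
  H <- qubit_hamiltonian(integrals)
  psi0 <- reference_state(integrals)
  Hd <- pauli_dense(H)
  objective <- function(theta) {
    psi <- uccsd_state_fast(gens, theta, psi0)
    Re(Conj(psi) %*% (Hd %*% psi))[1]
  }
  theta0 <- rep(0, length(gens))
  if (!length(theta0)) {
    return(new_ansatz_state(numeric(0), psi0, H))
  }
  # BFGS with finite-difference gradients stalls ~1e-6 from the minimum on
  # ill-scaled instances (amplitudes can be O(10) for unscaled synthetic
  # integrals); a deterministic simplex polish finishes the convergence
  fit <- stats::optim(theta0, objective, method = "BFGS",
                      control = list(reltol = tol, maxit = maxit,
                                     ndeps = rep(1e-7, length(theta0))))
  for (polish in 1:8) {
    refit <- stats::optim(fit$par, objective, method = "Nelder-Mead",
                          control = list(reltol = 1e-15, maxit = maxit * 10L))
    gain <- fit$value - refit$value
    fit <- refit
    if (gain < max(tol * abs(fit$value), 1e-12)) break
  }
  state <- uccsd_state_fast(gens, fit$par, psi0)
  new_ansatz_state(fit$par, state, H,
                   converged = fit$convergence == 0L,
                   message = if (fit$convergence != 0L)
                     paste("optimizer did not converge:", fit$convergence))
}

#' Serialize an ansatz state to JSON (parameters and energy)
#' @param state an `ansatz_state`.
#' @param path output file path.
#' @export
write_ansatz_state <- function(state, path) {
  jsonlite::write_json(list(parameters = state$parameters,
                            energy = state$energy,
                            converged = isTRUE(state$converged)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
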