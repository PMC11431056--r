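#' Low-temperature Gibbs state from an eigenpair list
#'
#' Builds `rho = sum_n w_n |n><n|` with Boltzmann weights
#' `w_n = exp(-beta (E_n - E_min))`, normalized explicitly by the partition
#' function over the retained spectrum (the energy shift guards against
#' overflow at large `beta`).  The supplied states need not be orthogonal
#' (reconstructed states with finite sampling noise are not); the density
#' matrix is trace-renormalized after assembly and the Gram matrix of the
#' states is attached as a diagnostic.
#'
#' @param energies real energies in Hartree.
#' @param states list of unit-norm state vectors (or a matrix of columns).
#' @param beta inverse temperature in inverse Hartree (non-negative).
#' @return an object of class `thermal_ensemble`: fields `beta`, `energies`,
#'   `weights`, `rho` (dense, Hermitian, unit trace), `gram`.
#' @export
thermal_state <- function(energies, states, beta) {
  if (!length(energies)) stop_arg("empty spectrum")
  if (is.matrix(states)) states <- lapply(seq_len(ncol(states)),
                                          function(k) states[, k])
  stopifnot(length(states) == length(energies))
  if (beta < 0) stop_arg("beta must be non-negative")
  w <- exp(-beta * (energies - min(energies)))
  w <- w / sum(w)
  d <- length(states[[1]])
  rho <- matrix(0 + 0i, d, d)
  for (n in seq_along(states))
    if (w[n] > 0) rho <- rho + w[n] * outer(states[[n]], Conj(states[[n]]))
  rho <- (rho + Conj(t(rho))) / 2
  rho <- rho / Re(sum(diag(rho)))
  gram <- vapply(states, function(a)
    vapply(states, function(b) sum(Conj(a) * b), complex(1)), complex(length(states)))
  structure(list(beta = beta, energies = energies, weights = w,
                 rho = rho, gram = gram),
            class = "thermal_ensemble")
}

#' @export
print.thermal_ensemble <- function(x, ...) {
  cat(sprintf("<thermal_ensemble: beta = %g /Ha, %d states, dim %d>\n",
              x$beta, length(x$energies), nrow(x$rho)))
  invisible(x)
}

as_density <- function(x) {
  if (inherits(x, "thermal_ensemble")) x$rho else as.matrix(x)
}

#' Trace distance between density matrices
#'
#' `D(rho, sigma) = Tr|rho - sigma| / 2`, i.e. half the sum of singular
#' values of the difference; lies in `[0, 1]` for unit-trace states.
#'
#' @param rho,sigma density matrices or [thermal_state()] ensembles of
#'   equal dimension.
#' @export
trace_distance <- function(rho, sigma) {
  r <- as_density(rho); s <- as_density(sigma)
  if (!all(dim(r) == dim(s))) stop_arg("dimension mismatch")
  0.5 * sum(svd(r - s)$d)
}

#' Thermal-average energy of an ensemble
#'
#' Returns `Tr[rho H]` in Hartree.  The benchmark quantity `DeltaE` of the
#' workflow is the absolute difference of this value between the ideal and
#' the reconstructed ensemble at the same `beta`.
#'
#' @param ensemble a [thermal_state()] result (or a density matrix).
#' @param H the Hamiltonian as a [pauli_sum()] or dense matrix.
#' @export
thermal_energy <- function(ensemble, H) {
  rho <- as_density(ensemble)
  if (inherits(H, "pauli_sum")) return(Re(pauli_expect_rho(H, rho)))
  Re(sum(t(H) * rho))
}

#' Exact sector Gibbs reference
#'
#' Convenience wrapper: the Gibbs state over all eigenstates of a
#' particle-number sector, embedded in the full register Hilbert space.
#' @param sector a [exact_eigenstates()] result.
#' @param beta inverse temperature (1/Ha).
#' @export
sector_gibbs <- function(sector, beta)
  thermal_state(sector$energies, sector$states, beta)
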