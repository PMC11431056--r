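#' Particle-number-conserving excitation basis
#'
#' Enumerates all spin-orbital single excitations `a_m^ a_i` (`i` occupied,
#' `m` virtual in the Hartree-Fock reference, with no spin restriction, so
#' spin-flip singles are included) and all doubles `a_m^ a_n^ a_i a_j` with
#' `m < n`, `i < j`.  Singles precede doubles; ordering is deterministic
#' (row-major over sorted index tuples).  This operator pool is deliberately
#' larger than the spin-preserving UCCSD amplitude set: it is the excitation
#' subspace of the equation-of-motion method, and its size `n` fixes the
#' measurement budget at `4 n^2` matrix-element observables.
#'
#' @param n_electrons electrons in the active space (`0 < n_e < 2 n_o`
#'   for a non-empty basis).
#' @param n_spatial_orbitals active spatial orbitals.
#' @return an object of class `excitation_basis`: fields `operators`
#'   (list of [fermion_op()]), `labels` (tibble with `order`, `indices`),
#'   `pauli` (Jordan-Wigner images), `n_qubits`.
#' @export
excitation_basis <- function(n_electrons, n_spatial_orbitals) {
  n <- as.integer(n_spatial_orbitals)
  nm <- 2L * n
  na <- ceiling(n_electrons / 2)
  nb <- n_electrons - na
  occ <- sort(c(seq_len(na) - 1L, n + seq_len(nb) - 1L))
  virt <- sort(setdiff(0:(nm - 1L), occ))
  terms <- character(0); ord <- integer(0); idx <- list()
  if (length(occ) && length(virt)) {
    for (i in occ) for (m in virt) {
      terms <- c(terms, sprintf("%d^ %d", m, i))
      ord <- c(ord, 1L); idx <- c(idx, list(c(m = m, i = i)))
    }
    no <- length(occ); nv <- length(virt)
    if (no >= 2L && nv >= 2L)
      for (ii in seq_len(no - 1L)) for (jj in (ii + 1L):no)
        for (mm in seq_len(nv - 1L)) for (nn in (mm + 1L):nv) {
          terms <- c(terms, sprintf("%d^ %d^ %d %d", virt[mm], virt[nn],
                                    occ[ii], occ[jj]))
          ord <- c(ord, 2L)
          idx <- c(idx, list(c(m = virt[mm], n = virt[nn],
                               i = occ[ii], j = occ[jj])))
        }
  }
  ops <- lapply(terms, fermion_op)
  structure(list(operators = ops,
                 labels = tibble::tibble(
                   order = ord,
                   indices = idx,
                   term = terms),
                 pauli = lapply(ops, jordan_wigner, n_modes = nm),
                 n_qubits = nm,
                 occupied = occ, virtual = virt),
            class = "excitation_basis")
}

#' @export
print.excitation_basis <- function(x, ...) {
  cat(sprintf("<excitation_basis: %d operators (%d singles, %d doubles) on %d qubits>\n",
              length(x$operators), sum(x$labels$order == 1L),
              sum(x$labels$order == 2L), x$n_qubits))
  invisible(x)
}

#' @export
length.excitation_basis <- function(x) length(x$operators)

#' Equation-of-motion observable set
#'
#' Binds a Hamiltonian to an excitation basis and represents the four
#' matrices of ground-state expectation values
#' `M[mu,nu] = <[E_mu^, H, E_nu]>`, `Q[mu,nu] = -<[E_mu^, H, E_nu^]>`
#' (three-argument symmetrized double commutators), and
#' `V[mu,nu] = <[E_mu^, E_nu]>`, `W[mu,nu] = -<[E_mu^, E_nu^]>` (single
#' commutators).  The total measurement load is `4 n^2` matrix-element
#' observables for a basis of size `n`; individual observables can be
#' materialized as Pauli sums with [eom_observable()], while bulk
#' evaluation ([evaluate_exact()], [estimate_matrix_elements()]) contracts
#' the same commutators against a density operator with dense linear
#' algebra, which is algebraically identical.
#'
#' @param H Hermitian [pauli_sum()] Hamiltonian.
#' @param basis an [excitation_basis()] on the same register.
#' @return an object of class `eom_observables` with field
#'   `n_observables = 4 * length(basis)^2`.
#' @export
build_eom_observables <- function(H, basis) {
  if (!pauli_is_hermitian(H)) stop_arg("H must be Hermitian")
  if (H$n_qubits != basis$n_qubits)
    stop_arg("Hamiltonian and basis act on different registers")
  structure(list(H = H, basis = basis,
                 n_observables = as.integer(4L * length(basis)^2),
                 engine = new.env(parent = emptyenv())),
            class = "eom_observables")
}

#' @export
print.eom_observables <- function(x, ...) {
  cat(sprintf("<eom_observables: basis %d, %d matrix-element observables>\n",
              length(x$basis), x$n_observables))
  invisible(x)
}

#' @rdname build_eom_observables
#' @param obs an `eom_observables` object.
#' @param which one of `"M"`, `"Q"`, `"V"`, `"W"`.
#' @param mu,nu 1-based basis indices.
#' @return [eom_observable()]: the requested observable as a [pauli_sum()].
#' @export
eom_observable <- function(obs, which = c("M", "Q", "V", "W"), mu, nu) {
  which <- match.arg(which)
  Emu_d <- pauli_dagger_op(obs$basis, mu)
  Env <- obs$basis$pauli[[nu]]
  Env_d <- pauli_dagger_op(obs$basis, nu)
  switch(which,
         M = double_commutator(Emu_d, obs$H, Env),
         Q = -1 * double_commutator(Emu_d, obs$H, Env_d),
         V = pauli_comm(Emu_d, Env),
         W = -1 * pauli_comm(Emu_d, Env_d))
}

pauli_dagger_op <- function(basis, mu) pauli_dagger(basis$pauli[[mu]])

# dense rho-independent contraction data, cached on the observable set
eom_engine <- function(obs) {
  env <- obs$engine
  if (!is.null(env$matE)) return(env)
  check_dense_cap(obs$basis$n_qubits)
  d <- 2^obs$basis$n_qubits
  nb <- length(obs$basis)
  Hd <- pauli_dense(obs$H)
  env$Hd <- Hd
  env$Ed <- lapply(obs$basis$pauli, pauli_dense)
  env$Ad <- lapply(env$Ed, function(E) Hd %*% E - E %*% Hd)  # [H, E_nu]
  vecc <- function(lst) vapply(lst, as.vector, complex(d * d))
  env$matE <- vecc(env$Ed)
  env$matEd <- vapply(env$Ed, function(E) as.vector(Conj(t(E))), complex(d * d))
  env$matA <- vecc(env$Ad)
  env$matAd <- vapply(env$Ad, function(A) as.vector(Conj(t(A))), complex(d * d))
  env
}

# fill M, Q, V, W by contracting the commutator observables against rho
eval_eom_matrices <- function(obs, rho) {
  env <- eom_engine(obs)
  d2 <- nrow(env$matE)
  nb <- length(obs$basis)
  PhiT <- matrix(0 + 0i, nb, d2)  # row mu: vec(t(rho A_mu^ - A_mu^ rho))
  RT <- matrix(0 + 0i, nb, d2)    # row mu: vec(t(rho E_mu^ - E_mu^ rho))
  for (mu in seq_len(nb)) {
    Edag <- Conj(t(env$Ed[[mu]]))
    Adag <- Conj(t(env$Ad[[mu]]))
    PhiT[mu, ] <- as.vector(t(rho %*% Adag - Adag %*% rho))
    RT[mu, ] <- as.vector(t(rho %*% Edag - Edag %*% rho))
  }
  M <- 0.5 * (PhiT %*% env$matE + RT %*% env$matA)
  Q <- -0.5 * (PhiT %*% env$matEd - RT %*% env$matAd)
  V <- RT %*% env$matE
  W <- -(RT %*% env$matEd)
  e0 <- sum(t(env$Hd) * rho)
  list(M = M, Q = Q, V = V, W = W, e0 = Re(e0))
}

new_eom_system <- function(mats, basis, source, se = NULL) {
  structure(list(M = mats$M, Q = mats$Q, V = mats$V, W = mats$W,
                 e0 = mats$e0, basis_size = length(basis),
                 labels = basis$labels, source = source, se = se,
                 excitation_energies = NULL, X = NULL, Y = NULL,
                 metric_rank = NA_integer_, flags = character(0)),
            class = "eom_system")
}

#' @export
print.eom_system <- function(x, ...) {
  cat(sprintf("<eom_system: basis %d, source '%s'%s>\n", x$basis_size,
              x$source,
              if (is.null(x$excitation_energies)) " (GEP unsolved)"
              else sprintf(", %d excitation energies",
                           length(x$excitation_energies))))
  if (!is.null(x$excitation_energies))
    cat("  E_0n (Ha):",
        format(utils::head(x$excitation_energies, 8), digits = 8), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Exact (infinite-sampling) expectation values of the EOM observables
#'
#' Fills the M, Q, V, W matrices with exact ground-state expectations,
#' the idealized infinite-shot limit of the measurement procedure.
#'
#' @param obs an [build_eom_observables()] set.
#' @param state unit-norm ground-state vector.
#' @return an `eom_system` with filled matrices (GEP not yet solved).
#' @export
evaluate_exact <- function(obs, state) {
  check_normalized(state)
  rho <- outer(state, Conj(state))
  new_eom_system(eval_eom_matrices(obs, rho), obs$basis, "exact")
}

#' Estimate all EOM matrices from one shared SIC-POVM sample set
#'
#' Every matrix element of M, Q, V and W — `4 n^2` observables — is
#' estimated from the same outcome sequence via the dual-frame estimator:
#' the samples are reduced once to the frame-reconstructed density operator
#' ([shadow_density()]) and each observable is contracted against it, which
#' reproduces the per-sample weight average exactly.  The ground-state
#' energy estimate `<H>` from the same samples is recorded as `e0`.
#'
#' @inheritParams evaluate_exact
#' @param samples a [sample_outcomes()] result for the ground state.
#' @param povm the POVM that generated the samples.
#' @param errors if `"full"`, also computes the per-element standard-error
#'   diagnostic matrices by the per-sample weight route (quadratic cost in
#'   the basis size times shots; intended for small registers).
#' @param assume_real if `TRUE` (default), project the estimated matrices
#'   onto their real parts.  With real orbital integrals and a real ground
#'   state — the only case this package produces — every EOM matrix element
#'   is exactly real, so the imaginary part of the estimate is pure shot
#'   noise and discarding it is an unbiased variance reduction.
#' @return an `eom_system` with filled matrices and, when requested, a
#'   list `se` of standard-error matrices.
#' @export
estimate_matrix_elements <- function(obs, samples, povm = canonical_sic(),
                                     errors = c("none", "full"),
                                     assume_real = TRUE) {
  errors <- match.arg(errors)
  rho_hat <- shadow_density(samples, povm)
  mats <- eval_eom_matrices(obs, rho_hat)
  if (assume_real)
    for (nm in c("M", "Q", "V", "W")) mats[[nm]] <- Re(mats[[nm]]) + 0i
  sys <- new_eom_system(mats, obs$basis,
                        sprintf("sampled (S = %d, seed = %d)",
                                samples$S, samples$seed))
  if (errors == "full") {
    nb <- length(obs$basis)
    se <- lapply(c(M = "M", Q = "Q", V = "V", W = "W"), function(w) {
      m <- matrix(NA_real_, nb, nb)
      for (mu in seq_len(nb)) for (nu in seq_len(nb)) {
        wts <- observable_weights(eom_observable(obs, w, mu, nu), povm, samples)
        est <- estimate_expectation(wts)
        m[mu, nu] <- sqrt(est$std_error_real^2 + est$std_error_imag^2)
      }
      m
    })
    sys$se <- se
  }
  sys
}

#' Solve the EOM generalized eigenvalue problem
#'
#' Assembles the doubled block pencil with left-hand blocks
#' `[[M, Q], [Q*, M*]]` and indefinite Hermitian metric
#' `[[V, W], [-W*, -V*]]`, regularizes the metric by canonical
#' orthogonalization (eigendirections with `|lambda|` below
#' `metric_tol * max |lambda|` are discarded; the survivor count is
#' `metric_rank`), solves the reduced problem, and retains the positive
#' excitation branch: eigenvalues with real part above `branch_tol` and
#' relative imaginary part below `imag_tol`, sorted ascending.  Estimated
#' matrices are first repaired to their exact symmetry class (M, V
#' Hermitian; Q symmetric; W antisymmetric), the minimal fix for finite
#' sampling noise.  Solutions are normalized to unit metric norm
#' (`x^ S x = 1`) when that norm is positive.
#'
#' @param system an `eom_system` with filled matrices.
#' @param metric_tol relative cutoff for the metric regularization.
#' @param branch_tol absolute positivity threshold for retained energies.
#' @param imag_tol relative imaginary-part tolerance; eigenvalues beyond it
#'   are dropped and a conditioning flag is attached to the result.
#' @return the `eom_system` with `excitation_energies`, `X`, `Y`,
#'   `metric_rank` and `flags` filled.
#' @export
solve_gep <- function(system, metric_tol = 1e-8, branch_tol = 1e-10,
                      imag_tol = 1e-6) {
  M <- (system$M + Conj(t(system$M))) / 2
  V <- (system$V + Conj(t(system$V))) / 2
  Q <- (system$Q + t(system$Q)) / 2
  W <- (system$W - t(system$W)) / 2
  A <- rbind(cbind(M, Q), cbind(Conj(Q), Conj(M)))
  S <- rbind(cbind(V, W), cbind(-Conj(W), -Conj(V)))
  es <- eigen((S + Conj(t(S))) / 2, symmetric = TRUE)
  amax <- max(abs(es$values))
  if (amax == 0) stop_arg("metric is numerically rank-zero; degenerate problem")
  keep <- abs(es$values) >= metric_tol * amax
  if (!any(keep)) stop_arg("metric is numerically rank-zero; degenerate problem")
  flags <- character(0)
  U <- es$vectors[, keep, drop = FALSE]
  lam <- es$values[keep]
  Ar <- Conj(t(U)) %*% A %*% U
  G <- (1 / lam) * Ar  # row scaling = diag(1/lam) %*% Ar
  eg <- eigen(G)
  ev <- eg$values
  pos <- Re(ev) > branch_tol
  good_im <- abs(Im(ev)) <= imag_tol * pmax(abs(Re(ev)), branch_tol)
  if (any(pos & !good_im))
    flags <- c(flags, sprintf("%d positive-branch eigenvalues dropped for excess imaginary part",
                              sum(pos & !good_im)))
  sel <- which(pos & good_im)
  sel <- sel[order(Re(ev[sel]))]
  n <- system$basis_size
  Xm <- matrix(0 + 0i, n, length(sel))
  Ym <- matrix(0 + 0i, n, length(sel))
  for (k in seq_along(sel)) {
    x <- U %*% eg$vectors[, sel[k]]
    nrm <- Re(Conj(t(x)) %*% S %*% x)[1]
    if (nrm > 1e-12) {
      x <- x / sqrt(nrm)
    } else {
      flags <- c(flags, sprintf("solution %d has non-positive metric norm", k))
      x <- x / sqrt(sum(Mod(x)^2))
    }
    Xm[, k] <- x[seq_len(n)]
    Ym[, k] <- x[n + seq_len(n)]
  }
  system$excitation_energies <- Re(ev[sel])
  system$X <- Xm
  system$Y <- Ym
  system$metric_rank <- sum(keep)
  system$flags <- flags
  system
}

# full (unregularized, both-branch) pencil spectrum; used for the
# E -> -E pairing property and conditioning diagnostics
gep_full_spectrum <- function(system) {
  M <- (system$M + Conj(t(system$M))) / 2
  V <- (system$V + Conj(t(system$V))) / 2
  Q <- (system$Q + t(system$Q)) / 2
  W <- (system$W - t(system$W)) / 2
  A <- rbind(cbind(M, Q), cbind(Conj(Q), Conj(M)))
  S <- rbind(cbind(V, W), cbind(-Conj(W), -Conj(V)))
  eigen(solve(S, A), only.values = TRUE)$values
}

#' Reconstruct excited states from the GEP solution
#'
#' Applies `O_n^ = sum_mu X[mu, n] E_mu - Y[mu, n] E_mu^` to the ground
#' state and normalizes.  Because the finite excitation pool satisfies the
#' vacuum-annihilation ("killer") condition only approximately, the raw
#' candidate `O_n^ |0>` can carry a spurious component along the ground
#' state itself; that component is projected out by default, which restores
#' exact eigenvectors whenever the excitation energies are exact.  Members
#' of a (near-)degenerate energy group are then Gram-Schmidt
#' orthonormalized inside their shared eigenspace, so that degenerate
#' levels contribute a proper projector to the Gibbs sum.  Candidates with
#' norm below `norm_tol` are dropped (with a message); the indices of
#' retained solutions are attached as attribute `kept` so energies can be
#' matched.
#'
#' @param gs unit-norm ground-state vector.
#' @param basis the [excitation_basis()] used for the system.
#' @param system a solved `eom_system`.
#' @param norm_tol drop threshold for near-null candidates.
#' @param project_out_reference remove the ground-state component of each
#'   candidate before normalization.
#' @param orthonormalize_degenerate orthonormalize within groups of
#'   solutions whose energies agree to `degeneracy_tol`.
#' @param degeneracy_tol absolute energy tolerance for grouping (Hartree).
#' @return list of unit-norm state vectors with attribute `kept`.
#' @export
reconstruct_excited_states <- function(gs, basis, system, norm_tol = 1e-10,
                                       project_out_reference = TRUE,
                                       orthonormalize_degenerate = TRUE,
                                       degeneracy_tol = 1e-8) {
  if (is.null(system$X)) stop_arg("solve the GEP first")
  nsol <- ncol(system$X)
  Ev <- lapply(basis$pauli, pauli_apply, psi = gs)         # E_mu |0>
  Edv <- lapply(seq_along(basis$pauli),
                function(mu) pauli_apply(pauli_dagger_op(basis, mu), gs))
  states <- list(); kept <- integer(0); energies <- numeric(0)
  for (k in seq_len(nsol)) {
    v <- complex(length(gs))
    for (mu in seq_len(length(basis))) {
      if (system$X[mu, k] != 0) v <- v + system$X[mu, k] * Ev[[mu]]
      if (system$Y[mu, k] != 0) v <- v - system$Y[mu, k] * Edv[[mu]]
    }
    if (project_out_reference) v <- v - sum(Conj(gs) * v) * gs
    if (orthonormalize_degenerate) {
      # orthogonalize against earlier members of the same energy group
      for (p in which(abs(energies - system$excitation_energies[k]) <=
                      degeneracy_tol))
        v <- v - sum(Conj(states[[p]]) * v) * states[[p]]
    }
    nrm <- sqrt(sum(Mod(v)^2))
    if (nrm < norm_tol) {
      message(sprintf("dropping zero-norm excited-state candidate %d (norm %.2e)",
                      k, nrm))
      next
    }
    states <- c(states, list(v / nrm))
    kept <- c(kept, k)
    energies <- c(energies, system$excitation_energies[k])
  }
  if (!length(states)) warning("all excited-state candidates had zero norm")
  attr(states, "kept") <- kept
  states
}

#' Serialize an EOM system to a structured JSON file
#'
#' Stores the four matrices (split into real and imaginary parts), the
#' retained excitation energies and coefficient matrices, the metric rank
#' and conditioning flags.  `read_eom_system()` restores the object.
#'
#' @param system an `eom_system`.
#' @param path output file path.
#' @export
write_eom_system <- function(system, path) {
  cplx <- function(m) if (is.null(m)) NULL else
    list(re = Re(m), im = Im(m), dim = dim(m))
  payload <- list(basis_size = system$basis_size,
                  source = system$source, e0 = system$e0,
                  M = cplx(system$M), Q = cplx(system$Q),
                  V = cplx(system$V), W = cplx(system$W),
                  X = cplx(system$X), Y = cplx(system$Y),
                  excitation_energies = system$excitation_energies,
                  metric_rank = system$metric_rank, flags = system$flags)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_eom_system
#' @export
read_eom_system <- function(path) {
  y <- jsonlite::read_json(path, simplifyVector = TRUE)
  uncplx <- function(l) if (is.null(l) || is.null(l$dim)) NULL else
    matrix(complex(real = unlist(l$re), imaginary = unlist(l$im)),
           l$dim[1], l$dim[2])
  structure(list(M = uncplx(y$M), Q = uncplx(y$Q), V = uncplx(y$V),
                 W = uncplx(y$W), e0 = y$e0, basis_size = y$basis_size,
                 labels = NULL, source = y$source, se = NULL,
                 excitation_energies = y$excitation_energies,
                 X = uncplx(y$X), Y = uncplx(y$Y),
                 metric_rank = y$metric_rank %||% NA_integer_,
                 flags = y$flags %||% character(0)),
            class = "eom_system")
}

#' Tidy and summary methods for solved EOM systems
#'
#' `tidy()` returns one row per retained excitation with its energy;
#' `glance()` returns one-row diagnostics (basis size, observable count,
#' metric rank, flags).
#' @param x an `eom_system`.
#' @param ... unused.
#' @method tidy eom_system
#' @export
tidy.eom_system <- function(x, ...) {
  if (is.null(x$excitation_energies))
    return(tibble::tibble(state = integer(0), excitation_energy = numeric(0)))
  tibble::tibble(state = seq_along(x$excitation_energies),
                 excitation_energy = x$excitation_energies)
}

#' @rdname tidy.eom_system
#' @method glance eom_system
#' @export
glance.eom_system <- function(x, ...) {
  tibble::tibble(basis_size = x$basis_size,
                 n_observables = as.integer(4L * x$basis_size^2),
                 metric_rank = x$metric_rank,
                 n_retained = length(x$excitation_energies %||% numeric(0)),
                 e0_estimate = x$e0,
                 flagged = length(x$flags) > 0L)
}
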