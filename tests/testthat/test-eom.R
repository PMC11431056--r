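test_that("excitation pools have the forced sizes and ordering", {
  b22 <- excitation_basis(2, 2)
  expect_equal(length(b22), 5L)
  expect_equal(sum(b22$labels$order == 1), 4L)
  b44 <- excitation_basis(4, 4)
  expect_equal(length(b44), 52L)
  expect_equal(sum(b44$labels$order == 2), 36L)
  expect_equal(length(excitation_basis(2, 1)), 0L)
  # singles precede doubles and every operator conserves particle number
  expect_true(all(diff(b22$labels$order) >= 0))
  N <- number_operator(4)
  for (E in b22$pauli)
    expect_equal(n_terms(pauli_comm(N, E)), 0L)
})

test_that("observable counts follow the 4 n^2 law", {
  tab <- polyene_pi_integrals(2)
  H <- qubit_hamiltonian(tab)
  expect_equal(build_eom_observables(H, excitation_basis(2, 2))$n_observables,
               100L)
  for (case in list(c(2, 3), c(4, 3))) {
    b <- excitation_basis(case[1], case[2])
    no <- length(b$occupied); nv <- length(b$virtual)
    expect_equal(length(b), no * nv + choose(no, 2) * choose(nv, 2))
  }
})

test_that("bulk dense evaluation equals materialized observable expectations", {
  tab <- synthesize_integrals(2, 2, seed = 7)
  H <- qubit_hamiltonian(tab)
  basis <- excitation_basis(2, 2)
  obs <- build_eom_observables(H, basis)
  set.seed(401)
  psi <- random_state(4)
  sys <- evaluate_exact(obs, psi)
  for (w in c("M", "Q", "V", "W")) {
    for (idx in list(c(1, 1), c(2, 4), c(5, 3))) {
      O <- eom_observable(obs, w, idx[1], idx[2])
      expect_lt(Mod(sys[[w]][idx[1], idx[2]] - pauli_expect(O, psi)), 1e-10)
    }
  }
  expect_lt(max(Mod(sys$M - Conj(t(sys$M)))), 1e-10)
  expect_lt(max(Mod(sys$V - Conj(t(sys$V)))), 1e-10)
})

test_that("the metric on the reference determinant is the identity", {
  tab <- polyene_pi_integrals(2)
  H <- qubit_hamiltonian(tab)
  basis <- excitation_basis(2, 2)
  obs <- build_eom_observables(H, basis)
  hf <- reference_state(tab)
  sys <- evaluate_exact(obs, hf)
  expect_close(sys$V[1:4, 1:4], diag(4), 1e-10)  # singles block
  expect_close(sys$W, matrix(0, 5, 5), 1e-10)
})

test_that("the decoupled diagonal pencil is solved exactly", {
  sys <- structure(list(M = diag(c(0.3, 0.9)) + 0i,
                        Q = matrix(0 + 0i, 2, 2),
                        V = diag(2) + 0i, W = matrix(0 + 0i, 2, 2),
                        e0 = 0, basis_size = 2L, labels = NULL,
                        source = "manual", se = NULL,
                        excitation_energies = NULL, X = NULL, Y = NULL,
                        metric_rank = NA_integer_, flags = character(0)),
                   class = "eom_system")
  out <- solve_gep(sys)
  expect_equal(out$excitation_energies, c(0.3, 0.9), tolerance = 1e-12)
  expect_close(Mod(out$X), diag(2), 1e-10)
  expect_close(out$Y, matrix(0, 2, 2), 1e-10)
  expect_equal(out$metric_rank, 4L)
  sys$V <- matrix(0 + 0i, 2, 2)
  expect_error(solve_gep(sys), "rank-zero")
})

test_that("qEOM with exact inputs reproduces 2-electron spectra exactly", {
  for (sd in c(7, 13)) {
    tab <- synthesize_integrals(2, 2, seed = sd)
    H <- qubit_hamiltonian(tab)
    sec <- exact_eigenstates(H, 2)
    gs <- sec$states[, 1]
    basis <- excitation_basis(2, 2)
    sys <- solve_gep(evaluate_exact(build_eom_observables(H, basis), gs))
    gaps <- sec$energies[-1] - sec$energies[1]
    expect_equal(length(sys$excitation_energies), length(gaps))
    expect_lt(max(abs(sort(sys$excitation_energies) - sort(gaps))), 1e-8)
    # reconstructed states match the exact eigen-subspaces
    st <- suppressMessages(reconstruct_excited_states(gs, basis, sys))
    Nd <- pauli_dense(number_operator(4))
    for (k in seq_along(st)) {
      E <- sys$excitation_energies[attr(st, "kept")[k]]
      grp <- which(abs((sec$energies - sec$energies[1]) - E) < 1e-6)
      fid <- sum(Mod(Conj(t(sec$states[, grp, drop = FALSE])) %*% st[[k]])^2)
      expect_gt(fid, 1 - 1e-8)
      expect_lt(abs(Re(Conj(st[[k]]) %*% Nd %*% st[[k]]) - 2), 1e-8)
    }
  }
})

test_that("the unregularized pencil spectrum pairs as E <-> -E", {
  tab <- synthesize_integrals(2, 2, seed = 7)
  H <- qubit_hamiltonian(tab)
  gs <- exact_eigenstates(H, 2)$states[, 1]
  sys <- evaluate_exact(build_eom_observables(H, excitation_basis(2, 2)), gs)
  ev <- sort(Re(qeomtherm:::gep_full_spectrum(sys)))
  expect_lt(max(abs(ev + rev(ev))), 1e-8)
})

test_that("one-hot solutions reconstruct single excitation images", {
  tab <- polyene_pi_integrals(2)
  basis <- excitation_basis(2, 2)
  gs <- reference_state(tab)
  sys <- structure(list(basis_size = 5L,
                        excitation_energies = 1,
                        X = matrix(c(0, 1, 0, 0, 0) + 0i, 5, 1),
                        Y = matrix(0 + 0i, 5, 1)),
                   class = "eom_system")
  st <- reconstruct_excited_states(gs, basis, sys,
                                   project_out_reference = FALSE)
  want <- pauli_apply(basis$pauli[[2]], gs)
  expect_close(st[[1]], want / sqrt(sum(Mod(want)^2)), 1e-12)
})

test_that("Rayleigh quotient of exact projector operators gives the gaps", {
  tab <- synthesize_integrals(2, 2, seed = 7)
  H <- qubit_hamiltonian(tab)
  Hd <- pauli_dense(H)
  sec <- exact_eigenstates(H, 2)
  gs <- sec$states[, 1]
  rho <- outer(gs, Conj(gs))
  for (n in c(2, 5, 6)) {
    Ond <- outer(sec$states[, n], Conj(gs))     # O_n^ = |n><0|
    On <- Conj(t(Ond))
    num <- sum(diag(rho %*% dense_dcomm(On, Hd, Ond)))
    den <- sum(diag(rho %*% dense_comm(On, Ond)))
    expect_equal(Re(num / den), sec$energies[n] - sec$energies[1],
                 tolerance = 1e-8)
  }
})

test_that("solved systems round-trip through JSON", {
  tab <- synthesize_integrals(2, 2, seed = 7)
  H <- qubit_hamiltonian(tab)
  gs <- exact_eigenstates(H, 2)$states[, 1]
  sys <- solve_gep(evaluate_exact(build_eom_observables(H,
                                                        excitation_basis(2, 2)), gs))
  f <- withr::local_tempfile(fileext = ".json")
  write_eom_system(sys, f)
  back <- read_eom_system(f)
  expect_close(back$M, sys$M, 1e-12)
  expect_close(back$X, sys$X, 1e-12)
  expect_equal(back$excitation_energies, sys$excitation_energies)
  expect_equal(back$metric_rank, sys$metric_rank)
})
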