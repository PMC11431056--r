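test_that("canonical SIC effects satisfy completeness and symmetry", {
  povm <- canonical_sic()
  expect_close(Reduce(`+`, povm$effects), diag(2), 1e-12)
  for (i in 1:4) {
    ev <- eigen(povm$effects[[i]], symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-14)
    for (j in 1:4) {
      ov <- Re(sum(diag((2 * povm$effects[[i]]) %*% (2 * povm$effects[[j]]))))
      expect_equal(ov, (2 * (i == j) + 1) / 3, tolerance = 1e-12)
    }
  }
})

test_that("closed-form duals agree with numerical frame inversion", {
  povm <- canonical_sic()
  num <- numerical_duals_oracle(povm)
  for (m in 1:4) expect_close(povm$duals[[m]], num[[m]], 1e-10)
  # dual reconstruction on a full single-qubit operator basis
  for (O in qeomtherm:::pauli_matrices()) {
    R <- Reduce(`+`, lapply(1:4, function(m)
      sum(diag(povm$duals[[m]] %*% O)) * povm$effects[[m]]))
    expect_close(R, O, 1e-12)
  }
  # and by tensor extension on random 2-qubit operators
  set.seed(501)
  for (rep in 1:3) {
    O <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4, 4)
    eff2 <- list(); dual2 <- list()
    k <- 0
    for (m2 in 1:4) for (m1 in 1:4) {
      k <- k + 1
      eff2[[k]] <- kronecker(povm$effects[[m2]], povm$effects[[m1]])
      dual2[[k]] <- kronecker(povm$duals[[m2]], povm$duals[[m1]])
    }
    R <- Reduce(`+`, lapply(1:16, function(m)
      sum(diag(dual2[[m]] %*% O)) * eff2[[m]]))
    expect_close(R, O, 1e-10)
  }
})

test_that("outcome distributions match direct overlap computation", {
  p <- outcome_distribution(c(1, 0) + 0i)
  expect_equal(p, c(1/2, 1/6, 1/6, 1/6), tolerance = 1e-12)
  # uniform ensemble average (maximally mixed) gives the flat distribution
  p_mix <- (outcome_distribution(c(1, 0) + 0i) +
            outcome_distribution(c(0, 1) + 0i)) / 2
  expect_equal(p_mix, rep(1/4, 4), tolerance = 1e-12)
  set.seed(502)
  psi <- random_state(3)
  p3 <- outcome_distribution(psi)
  expect_equal(sum(p3), 1, tolerance = 1e-12)
  expect_gte(min(p3), 0)
  expect_error(outcome_distribution(c(1, 1) + 0i), "normalized")
})

test_that("sampling is seeded, i.i.d. from the enumerated distribution", {
  psi <- c(1, 0) + 0i
  s1 <- sample_outcomes(psi, canonical_sic(), S = 200, seed = 3)
  s2 <- sample_outcomes(psi, canonical_sic(), S = 200, seed = 3)
  expect_identical(s1$outcomes, s2$outcomes)
  expect_error(sample_outcomes(psi, canonical_sic(), S = 0, seed = 1), "S must")
  # 5-sigma binomial bound on outcome 0 at S = 1e5
  s <- sample_outcomes(psi, canonical_sic(), S = 1e5, seed = 11)
  f0 <- mean(s$outcomes[, 1] == 0L)
  expect_lt(abs(f0 - 0.5), 5 * sqrt(0.25 / 1e5))
  # product state: per-qubit marginals match single-qubit distributions
  set.seed(503)
  a <- random_state(1); b <- random_state(1)
  prod_state <- kronecker(b, a)  # qubit 0 = a (fast index), qubit 1 = b
  sp <- sample_outcomes(prod_state, canonical_sic(), S = 2e4, seed = 12)
  for (q in 1:2) {
    marg <- outcome_distribution(if (q == 1) a else b)
    for (m in 0:3) {
      fh <- mean(sp$outcomes[, q] == m)
      expect_lt(abs(fh - marg[m + 1]),
                5 * sqrt(marg[m + 1] * (1 - marg[m + 1]) / 2e4) + 1e-12)
    }
  }
})

test_that("the chain-rule sampler draws from the same distribution", {
  set.seed(504)
  psi <- random_state(9)  # above the enumeration cap
  s <- sample_outcomes(psi, canonical_sic(), S = 5e3, seed = 21)
  expect_equal(dim(s$outcomes), c(5e3, 9))
  # qubit-0 marginal vs the exact reduced-state distribution
  rho0 <- matrix(0 + 0i, 2, 2)
  for (r in 0:1) for (c in 0:1) {
    ir <- seq(r, 2^9 - 1, by = 2); ic <- seq(c, 2^9 - 1, by = 2)
    rho0[r + 1, c + 1] <- sum(psi[ir + 1] * Conj(psi[ic + 1]))
  }
  povm <- canonical_sic()
  for (m in 0:3) {
    pm <- Re(sum(diag(rho0 %*% povm$effects[[m + 1]])))
    fh <- mean(s$outcomes[, 1] == m)
    expect_lt(abs(fh - pm), 5 * sqrt(pm * (1 - pm) / 5e3) + 1e-12)
  }
})

test_that("dual-frame weights take their enumerated values", {
  povm <- canonical_sic()
  en <- enumerated_outcomes(1)
  expect_equal(Re(observable_weights(pauli_identity(1), povm, en)),
               rep(1, 4), tolerance = 1e-12)
  wz <- Re(observable_weights(pauli_sum("Z"), povm, en))
  expect_equal(wz, c(3, -1, -1, -1), tolerance = 1e-12)
  w2 <- Re(observable_weights(2 * pauli_sum("Z"), povm, en))
  expect_equal(w2, 2 * wz, tolerance = 1e-12)
})

test_that("the estimator and its error formula are calibrated", {
  est <- estimate_expectation(rep(4 + 0i, 50))
  expect_equal(Re(est$estimate), 4)
  expect_equal(est$std_error_real, 0)
  expect_true(is.na(estimate_expectation(1 + 0i)$std_error_real))
  # <Z> on |0>: population mean 1, population SE exactly 2/sqrt(S)
  p <- outcome_distribution(c(1, 0) + 0i)
  w <- Re(observable_weights(pauli_sum("Z"), canonical_sic(),
                             enumerated_outcomes(1)))
  expect_equal(sum(p * w), 1, tolerance = 1e-12)
  popvar <- sum(p * w^2) - sum(p * w)^2
  expect_equal(popvar, 4, tolerance = 1e-12)
  # sampled estimate within 5 population SE
  s <- sample_outcomes(c(1, 0) + 0i, canonical_sic(), S = 1e4, seed = 5)
  est <- estimate_expectation(observable_weights(pauli_sum("Z"),
                                                 canonical_sic(), s))
  expect_lt(abs(Re(est$estimate) - 1), 5 * 2 / sqrt(1e4))
})

test_that("the estimator is unbiased by exact enumeration", {
  set.seed(505)
  povm <- canonical_sic()
  for (nq in c(2, 3)) {
    psi <- random_state(nq)
    O <- random_pauli_sum(nq, 5)
    p <- outcome_distribution(psi, povm)
    w <- observable_weights(O, povm, enumerated_outcomes(nq))
    expect_lt(Mod(sum(p * w) - pauli_expect(O, psi)), 1e-10)
  }
})

test_that("empirical estimator variance matches the enumerated formula", {
  povm <- canonical_sic()
  p <- outcome_distribution(c(1, 0) + 0i)
  S <- 100L
  ests <- vapply(1:1000, function(r) {
    s <- sample_outcomes(c(1, 0) + 0i, povm, S = S, seed = 7000 + r)
    mean(Re(observable_weights(pauli_sum("Z"), povm, s)))
  }, numeric(1))
  expect_lt(abs(var(ests) - 4 / S) / (4 / S), 0.15)
})

test_that("shadow reconstruction reproduces per-sample weight averages", {
  tab <- polyene_pi_integrals(2)
  H <- qubit_hamiltonian(tab)
  basis <- excitation_basis(2, 2)
  obs <- build_eom_observables(H, basis)
  gs <- exact_eigenstates(H, 2)$states[, 1]
  povm <- canonical_sic()
  s <- sample_outcomes(gs, povm, S = 500, seed = 9)
  rho_hat <- shadow_density(s, povm)
  expect_lt(Mod(sum(diag(rho_hat)) - 1), 1e-12)
  sys <- estimate_matrix_elements(obs, s, assume_real = FALSE)
  for (w in c("M", "Q", "V", "W")) for (idx in list(c(1, 2), c(3, 5))) {
    O <- eom_observable(obs, w, idx[1], idx[2])
    direct <- mean(observable_weights(O, povm, s))
    expect_lt(Mod(sys[[w]][idx[1], idx[2]] - direct), 1e-9)
  }
})

test_that("all matrices are estimated from one shared sample set", {
  tab <- polyene_pi_integrals(2)
  H <- qubit_hamiltonian(tab)
  obs <- build_eom_observables(H, excitation_basis(2, 2))
  gs <- exact_eigenstates(H, 2)$states[, 1]
  s <- sample_outcomes(gs, canonical_sic(), S = 1000, seed = 3)
  sys <- estimate_matrix_elements(obs, s, errors = "full")
  expect_equal(dim(sys$se$M), c(5, 5))
  expect_true(all(sys$se$V >= 0))
  # Hermitian pairs: estimates of (mu,nu) and (nu,mu) conjugates coincide
  # after symmetrization, and real-part projection keeps them real
  expect_true(all(Im(sys$M) == 0))
})

test_that("estimates converge to exact values with the shot budget", {
  tab <- polyene_pi_integrals(2)
  H <- qubit_hamiltonian(tab)
  obs <- build_eom_observables(H, excitation_basis(2, 2))
  gs <- exact_eigenstates(H, 2)$states[, 1]
  exact <- evaluate_exact(obs, gs)
  frob <- function(sys) sqrt(sum(Mod(sys$M - exact$M)^2) +
                             sum(Mod(sys$V - exact$V)^2))
  err <- sapply(1:10, function(r) {
    lo <- estimate_matrix_elements(obs, sample_outcomes(gs, canonical_sic(),
                                                        1e4, 600 + r))
    hi <- estimate_matrix_elements(obs, sample_outcomes(gs, canonical_sic(),
                                                        1e6, 700 + r))
    c(lo = frob(lo), hi = frob(hi))
  })
  expect_lt(median(err["hi", ]), median(err["lo", ]))
})

test_that("sample sets round-trip through CSV", {
  s <- sample_outcomes(random_state(2), canonical_sic(), S = 50, seed = 8,
                       state_id = "gs")
  f <- withr::local_tempfile(fileext = ".csv")
  write_sample_set(s, f)
  back <- read_sample_set(f)
  expect_identical(back$outcomes, s$outcomes)
  expect_equal(back$seed, 8L)
  expect_equal(back$state_id, "gs")
})
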