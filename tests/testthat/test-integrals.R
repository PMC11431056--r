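test_that("FCIDUMP records are echoed into the integral table", {
  f <- withr::local_tempfile(fileext = ".fcidump")
  writeLines(c("&FCI NORB=1,NELEC=2,MS2=0,", "&END",
               " 0.675   1 1 1 1",
               "-1.25    1 1 0 0",
               " 0.71    0 0 0 0"), f)
  tab <- read_fcidump(f)
  expect_equal(tab$n_spatial_orbitals, 1L)
  expect_equal(tab$n_electrons, 2L)
  expect_equal(tab$h1[1, 1], -1.25)
  expect_equal(tab$h2[1, 1, 1, 1], 0.675)
  expect_equal(tab$core_energy, 0.71)
})

test_that("write/read round trip is the identity", {
  tab <- synthesize_integrals(3, 4, seed = 5)
  f <- withr::local_tempfile(fileext = ".fcidump")
  write_fcidump(tab, f)
  tab2 <- read_fcidump(f)
  expect_equal(tab2$n_electrons, tab$n_electrons)
  expect_lt(max(abs(tab2$h1 - tab$h1)), 1e-12)
  expect_lt(max(abs(tab2$h2 - tab$h2)), 1e-12)
  expect_equal(tab2$core_energy, tab$core_energy, tolerance = 1e-12)
})

test_that("a single stored two-electron record fills all 8 permutations", {
  f <- withr::local_tempfile(fileext = ".fcidump")
  writeLines(c("&FCI NORB=2,NELEC=2,MS2=0,", "&END",
               " 0.25   2 1 1 1"), f)
  g <- qeomtherm:::physicist_to_chemist(read_fcidump(f)$h2)
  # the 8 permutations of (21|11) collapse onto 4 distinct index tuples
  perms <- list(c(2,1,1,1), c(1,2,1,1), c(1,1,2,1), c(1,1,1,2))
  for (p in perms) expect_equal(g[p[1], p[2], p[3], p[4]], 0.25)
  expect_equal(sum(g != 0), 4L)
})

test_that("malformed FCIDUMP input is rejected with line information", {
  f <- withr::local_tempfile(fileext = ".fcidump")
  writeLines(c("NOHEADER"), f)
  expect_error(read_fcidump(f), "header")
  writeLines(c("&FCI NORB=2,NELEC=2,", "&END", " 1.0  3 1 1 1"), f)
  expect_error(read_fcidump(f), "line 3")
  writeLines(c("&FCI NORB=2,NELEC=2,", "&END", " 1.0  1 1 1"), f)
  expect_error(read_fcidump(f), "5 fields")
})

test_that("synthetic integrals are deterministic and symmetric", {
  a <- synthesize_integrals(2, 2, seed = 7)
  b <- synthesize_integrals(2, 2, seed = 7)
  expect_identical(a, b)
  expect_error(synthesize_integrals(2, 5, seed = 1), "n_electrons")
  # invariants are enforced by the constructor; spot-check 8-fold symmetry
  g <- qeomtherm:::physicist_to_chemist(a$h2)
  expect_lt(max(abs(g - aperm(g, c(3, 4, 1, 2)))), 1e-12)
})

test_that("assembled Hamiltonians are Hermitian and number conserving", {
  for (tab in list(synthesize_integrals(3, 2, seed = 1),
                   polyene_pi_integrals(2))) {
    H <- qubit_hamiltonian(tab)
    expect_true(pauli_is_hermitian(H))
    Hd <- pauli_dense(H)
    Nd <- pauli_dense(number_operator(n_spin_orbitals(tab)))
    expect_lt(max(Mod(Hd %*% Nd - Nd %*% Hd)), 1e-10)
  }
})

test_that("Hamiltonian limiting cases are reproduced", {
  # all integrals zero: constant core operator
  tab0 <- integral_table(2, 2, core_energy = 0.37, h1 = matrix(0, 2, 2),
                         h2 = array(0, rep(2, 4)))
  H0 <- qubit_hamiltonian(tab0)
  expect_close(pauli_dense(H0), 0.37 * diag(16), 1e-14)
  # h1 = identity, h2 = 0: the total number operator
  tab1 <- integral_table(2, 2, 0, diag(2), array(0, rep(2, 4)))
  expect_close(pauli_dense(qubit_hamiltonian(tab1)),
               pauli_dense(number_operator(4)), 1e-13)
})

test_that("the second-quantized assembly matches a brute-force loop oracle", {
  tab <- synthesize_integrals(2, 2, seed = 7)
  n <- tab$n_spatial_orbitals
  d <- 2^(2 * n)
  oracle <- tab$core_energy * diag(d) + 0i
  for (p in 1:n) for (q in 1:n) for (sp in c(0, n))
    oracle <- oracle + tab$h1[p, q] *
      fermion_matrix_oracle(fermion_op(sprintf("%d^ %d",
                                               p - 1 + sp, q - 1 + sp)), 2 * n)
  for (p in 1:n) for (q in 1:n) for (r in 1:n) for (s in 1:n)
    for (s1 in c(0, n)) for (s2 in c(0, n)) {
      term <- sprintf("%d^ %d^ %d %d", p - 1 + s1, q - 1 + s2,
                      s - 1 + s2, r - 1 + s1)
      P <- p - 1 + s1; Q <- q - 1 + s2
      if (P == Q || (s - 1 + s2) == (r - 1 + s1)) next
      oracle <- oracle + 0.5 * tab$h2[p, q, r, s] *
        fermion_matrix_oracle(fermion_op(term), 2 * n)
    }
  expect_close(pauli_dense(qubit_hamiltonian(tab)), oracle, 1e-11)
})

test_that("shipped synthetic fixtures match their generators", {
  for (case in list(list(file = "ethylene_pi_cas22_synthetic.fcidump", n = 2),
                    list(file = "butadiene_pi_cas44_synthetic.fcidump", n = 4))) {
    path <- system.file("extdata", case$file, package = "qeomtherm")
    expect_true(nzchar(path))
    tab <- read_fcidump(path)
    ref <- polyene_pi_integrals(case$n)
    expect_lt(max(abs(tab$h1 - ref$h1)), 1e-12)
    expect_lt(max(abs(tab$h2 - ref$h2)), 1e-12)
  }
})

test_that("orbital rotation preserves the spectrum", {
  tab <- synthesize_integrals(2, 2, seed = 3)
  C <- qr.Q(qr(matrix(rnorm(4, 1), 2, 2)))
  rot <- rotate_orbitals(tab, C)
  e1 <- sort(eigen(pauli_dense(qubit_hamiltonian(tab)), symmetric = TRUE,
                   only.values = TRUE)$values)
  e2 <- sort(eigen(pauli_dense(qubit_hamiltonian(rot)), symmetric = TRUE,
                   only.values = TRUE)$values)
  expect_lt(max(abs(e1 - e2)), 1e-9)
})
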