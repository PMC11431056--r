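# Independent brute-force oracles, deliberately built on different code
# paths from the package internals.

# occupation-number-basis matrix of a single ladder operator a_p / a_p^
# with the fermionic sign (-1)^{n_0 + ... + n_{p-1}}
ladder_matrix_oracle <- function(p, dag, n_modes) {
  d <- 2^n_modes
  M <- matrix(0 + 0i, d, d)
  for (b in 0:(d - 1L)) {
    bits <- as.integer(intToBits(b))[1:n_modes]
    sign <- (-1)^sum(bits[seq_len(p)])  # parity of modes below p (0-based p)
    if (dag) {
      if (bits[p + 1L] == 0L) M[b + 2^p + 1L, b + 1L] <- sign
    } else {
      if (bits[p + 1L] == 1L) M[b - 2^p + 1L, b + 1L] <- sign
    }
  }
  M
}

# occupation-basis matrix of a fermion_op, by multiplying ladder matrices
fermion_matrix_oracle <- function(op, n_modes) {
  d <- 2^n_modes
  out <- matrix(0 + 0i, d, d)
  for (i in seq_along(op$coeff)) {
    term <- op$terms[i]
    M <- diag(d) + 0i
    if (nzchar(term)) {
      for (f in strsplit(term, " ", fixed = TRUE)[[1]]) {
        dag <- endsWith(f, "^")
        p <- as.integer(sub("\\^$", "", f))
        M <- M %*% ladder_matrix_oracle(p, dag, n_modes)
      }
    }
    out <- out + op$coeff[i] * M
  }
  out
}

# dense matrix of a pauli_sum via explicit Kronecker products
pauli_matrix_oracle <- function(ps) {
  sig <- list(I = diag(2) + 0i,
              X = matrix(c(0, 1, 1, 0), 2) + 0i,
              Y = matrix(c(0, 1i, -1i, 0), 2),
              Z = matrix(c(1, 0, 0, -1), 2) + 0i)
  d <- 2^ps$n_qubits
  out <- matrix(0 + 0i, d, d)
  labs <- pauli_labels(ps)
  for (i in seq_along(ps$coeff)) {
    M <- matrix(1 + 0i, 1, 1)
    for (q in seq_len(ps$n_qubits))  # qubit 0 = least significant factor
      M <- kronecker(sig[[substr(labs[i], q, q)]], M)
    out <- out + ps$coeff[i] * M
  }
  out
}

random_pauli_sum <- function(nq, nterms) {
  letters4 <- c("I", "X", "Y", "Z")
  strings <- replicate(nterms, paste0(sample(letters4, nq, TRUE), collapse = ""))
  pauli_sum(strings, complex(real = rnorm(nterms), imaginary = rnorm(nterms)))
}

random_state <- function(nq) {
  v <- complex(real = rnorm(2^nq), imaginary = rnorm(2^nq))
  v / sqrt(sum(Mod(v)^2))
}

random_fermion_op <- function(n_modes, nterms, max_factors = 3L) {
  terms <- replicate(nterms, {
    k <- sample.int(max_factors, 1)
    paste0(sample.int(n_modes, k, replace = TRUE) - 1L,
           ifelse(runif(k) > 0.5, "^", ""), collapse = " ")
  })
  fermion_op(terms, complex(real = rnorm(nterms), imaginary = rnorm(nterms)))
}

dense_comm <- function(A, B) A %*% B - B %*% A
dense_dcomm <- function(A, B, C)
  (dense_comm(dense_comm(A, B), C) + dense_comm(A, dense_comm(B, C))) / 2

# numerical dual-frame construction by inverting the frame superoperator;
# oracle for the closed-form duals D_i = 3 * (2 Pi_i) - I
numerical_duals_oracle <- function(povm) {
  P <- vapply(povm$effects, as.vector, complex(4))  # columns vec(Pi_m)
  D <- Conj(t(solve(P)))                            # P %*% D^H = I_4
  lapply(1:4, function(m) matrix(D[, m], 2, 2))
}

# all-outcome sample_set for exact enumeration of weights
enumerated_outcomes <- function(nq) {
  structure(list(outcomes = qeomtherm:::decode_outcomes(0:(4^nq - 1L), nq),
                 S = 4^nq, n_qubits = as.integer(nq), seed = NA_integer_,
                 state_id = "enumeration"),
            class = "sample_set")
}

expect_close <- function(a, b, tol = 1e-10) {
  expect_lt(max(Mod(as.complex(a) - as.complex(b))), tol)
}
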