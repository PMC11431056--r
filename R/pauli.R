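#' Pauli-string operator sums
#'
#' A `pauli_sum` is a complex-weighted sum of N-qubit Pauli strings, the
#' carrier for qubit Hamiltonians, excitation operators and every observable
#' estimated in the workflow.  Terms are stored in a symplectic binary
#' encoding: each string is a pair of bit masks `(x, z)` with
#' `P = i^{x.z} X^x Z^z`, so that products, commutators and dense-matrix
#' realizations are vectorized bit operations.  Qubit `q` corresponds to bit
#' `q` of the masks and to character position `q + 1` of a printed string
#' such as `"XZIY"`.
#'
#' @param strings character vector of Pauli strings over the alphabet
#'   `I`, `X`, `Y`, `Z`; all of the same length (the qubit count).
#' @param coeffs complex (or numeric) coefficients, one per string.
#' @param n_qubits number of qubits; inferred from `strings` when omitted.
#' @return an object of class `pauli_sum`.
#' @examples
#' H <- pauli_sum(c("ZI", "IZ", "XX"), c(0.5, 0.5, 0.25))
#' pauli_dense(H)
#' @export
pauli_sum <- function(strings, coeffs = rep(1, length(strings)),
                      n_qubits = NULL) {
  if (length(strings) == 0L) {
    if (is.null(n_qubits)) stop_arg("n_qubits required for an empty pauli_sum")
    return(new_pauli_sum(integer(0), integer(0), complex(0), n_qubits))
  }
  nq <- unique(nchar(strings))
  if (length(nq) != 1L) stop_arg("all Pauli strings must have equal length")
  if (!is.null(n_qubits) && n_qubits != nq)
    stop_arg("string length does not match n_qubits")
  if (nq > 24L) stop_arg("at most 24 qubits supported")
  x <- integer(length(strings)); z <- integer(length(strings))
  for (q in seq_len(nq)) {
    ch <- substr(strings, q, q)
    if (!all(ch %in% c("I", "X", "Y", "Z")))
      stop_arg("Pauli strings may only contain I, X, Y, Z")
    bit <- bitwShiftL(1L, q - 1L)
    x <- x + bit * as.integer(ch %in% c("X", "Y"))
    z <- z + bit * as.integer(ch %in% c("Y", "Z"))
  }
  new_pauli_sum(x, z, as.complex(coeffs), nq)
}

# low-level constructor: aggregates duplicate strings, drops exact zeros
new_pauli_sum <- function(x, z, coeff, n_qubits, aggregate = TRUE) {
  if (aggregate && length(x)) {
    key <- x * 2^n_qubits + z
    o <- order(key)
    x <- x[o]; z <- z[o]; coeff <- coeff[o]; key <- key[o]
    grp <- cumsum(!duplicated(key))
    if (grp[length(grp)] < length(key)) {
      re <- rowsum(Re(coeff), grp, reorder = FALSE)
      im <- rowsum(Im(coeff), grp, reorder = FALSE)
      keep <- !duplicated(key)
      x <- x[keep]; z <- z[keep]
      coeff <- complex(real = re[, 1], imaginary = im[, 1])
    }
    nz <- coeff != 0
    x <- x[nz]; z <- z[nz]; coeff <- coeff[nz]
  }
  structure(list(n_qubits = as.integer(n_qubits),
                 x = as.integer(x), z = as.integer(z), coeff = coeff),
            class = "pauli_sum")
}

#' @export
print.pauli_sum <- function(x, max_terms = 12L, ...) {
  cat(sprintf("<pauli_sum: %d qubits, %d terms>\n", x$n_qubits, length(x$coeff)))
  n <- min(length(x$coeff), max_terms)
  if (n) {
    lab <- pauli_labels(x)[seq_len(n)]
    for (i in seq_len(n))
      cat(sprintf("  %s  %s\n", lab[i], format(x$coeff[i], digits = 6)))
    if (length(x$coeff) > n) cat(sprintf("  ... %d more\n", length(x$coeff) - n))
  }
  invisible(x)
}

#' @rdname pauli_sum
#' @param ps a `pauli_sum`.
#' @export
pauli_labels <- function(ps) {
  if (!length(ps$x)) return(character(0))
  out <- matrix("I", length(ps$x), ps$n_qubits)
  for (q in seq_len(ps$n_qubits)) {
    xb <- bitwAnd(bitwShiftR(ps$x, q - 1L), 1L)
    zb <- bitwAnd(bitwShiftR(ps$z, q - 1L), 1L)
    out[, q] <- c("I", "X", "Z", "Y")[1L + xb + 2L * zb]
  }
  apply(out, 1L, paste0, collapse = "")
}

#' @rdname pauli_sum
#' @export
n_qubits <- function(ps) ps$n_qubits

#' @rdname pauli_sum
#' @export
n_terms <- function(ps) length(ps$coeff)

#' Tidy view of a Pauli sum
#'
#' @param x a [pauli_sum()].
#' @param ... unused.
#' @return a tibble with columns `string` and `coeff`.
#' @method tidy pauli_sum
#' @export
tidy.pauli_sum <- function(x, ...) {
  tibble::tibble(string = pauli_labels(x), coeff = x$coeff)
}

#' Identity and zero operators
#' @param n_qubits qubit count.
#' @param coeff coefficient of the identity string.
#' @export
pauli_identity <- function(n_qubits, coeff = 1 + 0i)
  new_pauli_sum(0L, 0L, as.complex(coeff), n_qubits)

#' @rdname pauli_identity
#' @export
pauli_zero <- function(n_qubits)
  new_pauli_sum(integer(0), integer(0), complex(0), n_qubits)

check_same_register <- function(a, b) {
  if (a$n_qubits != b$n_qubits)
    stop_arg("operators act on different qubit counts (",
             a$n_qubits, " vs ", b$n_qubits, ")")
}

#' @export
`+.pauli_sum` <- function(e1, e2) {
  if (is.numeric(e2) || is.complex(e2)) e2 <- pauli_identity(e1$n_qubits, e2)
  if (is.numeric(e1) || is.complex(e1)) e1 <- pauli_identity(e2$n_qubits, e1)
  check_same_register(e1, e2)
  new_pauli_sum(c(e1$x, e2$x), c(e1$z, e2$z), c(e1$coeff, e2$coeff), e1$n_qubits)
}

#' @export
`-.pauli_sum` <- function(e1, e2) {
  if (missing(e2)) return(new_pauli_sum(e1$x, e1$z, -e1$coeff, e1$n_qubits,
                                        aggregate = FALSE))
  e1 + (-1) * e2
}

#' @export
`*.pauli_sum` <- function(e1, e2) {
  if (is.numeric(e1) || is.complex(e1))
    return(new_pauli_sum(e2$x, e2$z, e1 * e2$coeff, e2$n_qubits,
                         aggregate = length(e1) == 1L && e1[1] == 0))
  if (is.numeric(e2) || is.complex(e2)) return(e2 * e1)
  pauli_mult(e1, e2)
}

# phase exponent of sigma_a * sigma_b = i^e sigma_{a xor b} (per-term vectors)
pauli_phase_exp <- function(x1, z1, x2, z2) {
  x3 <- bitwXor(x1, x2); z3 <- bitwXor(z1, z2)
  popcount(bitwAnd(x1, z1)) + popcount(bitwAnd(x2, z2)) -
    popcount(bitwAnd(x3, z3)) + 2L * popcount(bitwAnd(z1, x2))
}

#' Product of two Pauli sums
#' @param a,b `pauli_sum` objects on the same register.
#' @export
pauli_mult <- function(a, b) {
  check_same_register(a, b)
  na <- length(a$coeff); nb <- length(b$coeff)
  if (!na || !nb) return(pauli_zero(a$n_qubits))
  ia <- rep(seq_len(na), each = nb); ib <- rep(seq_len(nb), times = na)
  x1 <- a$x[ia]; z1 <- a$z[ia]; x2 <- b$x[ib]; z2 <- b$z[ib]
  ph <- i_power(pauli_phase_exp(x1, z1, x2, z2))
  new_pauli_sum(bitwXor(x1, x2), bitwXor(z1, z2),
                a$coeff[ia] * b$coeff[ib] * ph, a$n_qubits)
}

#' Commutator and double commutator of Pauli sums
#'
#' `pauli_comm(a, b)` returns `[a, b] = ab - ba`, skipping term pairs whose
#' strings commute.  `double_commutator(a, b, c)` returns the symmetrized
#' double commutator `([[a,b],c] + [a,[b,c]]) / 2` used for the
#' equation-of-motion matrix elements.
#'
#' @param a,b,c `pauli_sum` objects on the same register.
#' @export
pauli_comm <- function(a, b) {
  check_same_register(a, b)
  na <- length(a$coeff); nb <- length(b$coeff)
  if (!na || !nb) return(pauli_zero(a$n_qubits))
  ia <- rep(seq_len(na), each = nb); ib <- rep(seq_len(nb), times = na)
  x1 <- a$x[ia]; z1 <- a$z[ia]; x2 <- b$x[ib]; z2 <- b$z[ib]
  s <- (popcount(bitwAnd(x1, z2)) + popcount(bitwAnd(z1, x2))) %% 2L == 1L
  if (!any(s)) return(pauli_zero(a$n_qubits))
  x1 <- x1[s]; z1 <- z1[s]; x2 <- x2[s]; z2 <- z2[s]
  ph <- i_power(pauli_phase_exp(x1, z1, x2, z2))
  new_pauli_sum(bitwXor(x1, x2), bitwXor(z1, z2),
                2 * a$coeff[ia][s] * b$coeff[ib][s] * ph, a$n_qubits)
}

#' @rdname pauli_comm
#' @export
double_commutator <- function(a, b, c) {
  check_same_register(a, b); check_same_register(b, c)
  0.5 * (pauli_comm(pauli_comm(a, b), c) + pauli_comm(a, pauli_comm(b, c)))
}

#' Hermitian conjugate of a Pauli sum
#'
#' Pauli strings are self-adjoint, so conjugation acts on coefficients only;
#' a `pauli_sum` is Hermitian iff all its coefficients are real.
#' @param ps a `pauli_sum`.
#' @export
pauli_dagger <- function(ps)
  new_pauli_sum(ps$x, ps$z, Conj(ps$coeff), ps$n_qubits, aggregate = FALSE)

#' @rdname pauli_dagger
#' @param tol tolerance on imaginary parts.
#' @export
pauli_is_hermitian <- function(ps, tol = 1e-10)
  !length(ps$coeff) || max(abs(Im(ps$coeff))) < tol

DENSE_QUBIT_CAP <- 12L

check_dense_cap <- function(nq) {
  if (nq > DENSE_QUBIT_CAP)
    stop_arg("dense realization capped at ", DENSE_QUBIT_CAP,
             " qubits (requested ", nq, ")")
}

# per-term sparse action: sigma_{x,z}|b> = i^{pc(x&z)} (-1)^{pc(z&b)} |b xor x>
#' Dense matrix realization (occupation/computational basis)
#'
#' Basis state index `b` has the bit of qubit `q` at position `q`
#' (qubit 0 least significant).  Capped at 12 qubits.
#' @param ps a `pauli_sum`.
#' @export
pauli_dense <- function(ps) {
  check_dense_cap(ps$n_qubits)
  d <- 2^ps$n_qubits
  M <- matrix(0 + 0i, d, d)
  b <- 0:(d - 1L)
  for (t in seq_along(ps$coeff)) {
    x <- ps$x[t]; z <- ps$z[t]
    val <- ps$coeff[t] * i_power(popcount(bitwAnd(x, z))) *
      (1 - 2 * (popcount(bitwAnd(z, b)) %% 2L))
    M[cbind(bitwXor(b, x) + 1L, b + 1L)] <- M[cbind(bitwXor(b, x) + 1L, b + 1L)] + val
  }
  M
}

#' Apply a Pauli sum to a state vector
#' @param ps a `pauli_sum`.
#' @param psi complex state vector of length `2^n_qubits`.
#' @export
pauli_apply <- function(ps, psi) {
  d <- 2^ps$n_qubits
  if (length(psi) != d) stop_arg("state vector has wrong dimension")
  out <- complex(d)
  b <- 0:(d - 1L)
  for (t in seq_along(ps$coeff)) {
    x <- ps$x[t]; z <- ps$z[t]
    val <- ps$coeff[t] * i_power(popcount(bitwAnd(x, z))) *
      (1 - 2 * (popcount(bitwAnd(z, b)) %% 2L))
    idx <- bitwXor(b, x) + 1L
    out[idx] <- out[idx] + val * psi
  }
  out
}

#' Expectation value of a Pauli sum on a pure state
#' @inheritParams pauli_apply
#' @export
pauli_expect <- function(ps, psi) sum(Conj(psi) * pauli_apply(ps, psi))
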