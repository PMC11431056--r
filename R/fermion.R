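#' Second-quantized fermionic operators
#'
#' A `fermion_op` is a complex-weighted sum of ordered products of fermionic
#' creation/annihilation operators on spin-orbital modes.  Terms are written
#' in the conventional compact notation: `"3^ 1"` is `a3^dagger a1`, the
#' empty string is the identity.  Mode indices are 0-based and refer to
#' spin orbitals (block spin ordering: alpha spatial orbitals first, then
#' beta; see [build_fermionic_hamiltonian()]).
#'
#' @param terms character vector of operator products (factors separated by
#'   single spaces, `^` marking creation operators), or a list of integer
#'   index vectors paired with `dag` logical vectors.
#' @param coeffs complex coefficients, one per term.
#' @return an object of class `fermion_op`.
#' @examples
#' hop <- fermion_op(c("1^ 0", "0^ 1"), c(1, 1))   # a1^ a0 + a0^ a1
#' jordan_wigner(hop, n_modes = 2)
#' @export
fermion_op <- function(terms = character(0), coeffs = rep(1, length(terms))) {
  stopifnot(length(terms) == length(coeffs))
  terms <- as.character(terms)
  new_fermion_op(terms, as.complex(coeffs))
}

new_fermion_op <- function(terms, coeff) {
  if (length(terms)) {
    o <- order(terms)
    terms <- terms[o]; coeff <- coeff[o]
    grp <- cumsum(!duplicated(terms))
    if (grp[length(grp)] < length(terms)) {
      re <- rowsum(Re(coeff), grp, reorder = FALSE)
      im <- rowsum(Im(coeff), grp, reorder = FALSE)
      keep <- !duplicated(terms)
      terms <- terms[keep]
      coeff <- complex(real = re[, 1], imaginary = im[, 1])
    }
    nz <- coeff != 0
    terms <- terms[nz]; coeff <- coeff[nz]
  }
  structure(list(terms = terms, coeff = coeff), class = "fermion_op")
}

#' @export
print.fermion_op <- function(x, max_terms = 12L, ...) {
  cat(sprintf("<fermion_op: %d terms>\n", length(x$coeff)))
  n <- min(length(x$coeff), max_terms)
  for (i in seq_len(n))
    cat(sprintf("  [%s]  %s\n",
                if (nzchar(x$terms[i])) x$terms[i] else "1",
                format(x$coeff[i], digits = 6)))
  if (length(x$coeff) > n) cat(sprintf("  ... %d more\n", length(x$coeff) - n))
  invisible(x)
}

# parse "3^ 1" -> list(idx = c(3L, 1L), dag = c(TRUE, FALSE))
parse_factors <- function(term) {
  if (!nzchar(term)) return(list(idx = integer(0), dag = logical(0)))
  f <- strsplit(term, " ", fixed = TRUE)[[1]]
  dag <- endsWith(f, "^")
  list(idx = as.integer(sub("\\^$", "", f)), dag = dag)
}

unparse_factors <- function(idx, dag)
  paste0(idx, ifelse(dag, "^", ""), collapse = " ")

fermion_max_mode <- function(op) {
  m <- -1L
  for (t in op$terms) {
    p <- parse_factors(t)
    if (length(p$idx)) m <- max(m, p$idx)
  }
  m
}

#' @export
`+.fermion_op` <- function(e1, e2) {
  if (is.numeric(e2) || is.complex(e2)) e2 <- fermion_op("", e2)
  if (is.numeric(e1) || is.complex(e1)) e1 <- fermion_op("", e1)
  new_fermion_op(c(e1$terms, e2$terms), c(e1$coeff, e2$coeff))
}

#' @export
`-.fermion_op` <- function(e1, e2) {
  if (missing(e2)) return(new_fermion_op(e1$terms, -e1$coeff))
  e1 + (-1) * e2
}

#' @export
`*.fermion_op` <- function(e1, e2) {
  if (is.numeric(e1) || is.complex(e1))
    return(new_fermion_op(e2$terms, e1 * e2$coeff))
  if (is.numeric(e2) || is.complex(e2))
    return(new_fermion_op(e1$terms, e2 * e1$coeff))
  fermion_mult(e1, e2)
}

#' Product of fermionic operators (concatenation of factor strings)
#' @param a,b `fermion_op` objects.
#' @export
fermion_mult <- function(a, b) {
  if (!length(a$coeff) || !length(b$coeff)) return(fermion_op())
  ia <- rep(seq_along(a$coeff), each = length(b$coeff))
  ib <- rep(seq_along(b$coeff), times = length(a$coeff))
  terms <- paste(a$terms[ia], b$terms[ib])
  terms <- trimws(terms)
  new_fermion_op(terms, a$coeff[ia] * b$coeff[ib])
}

#' Hermitian conjugate of a fermionic operator
#' @param op a `fermion_op`.
#' @export
fermion_dagger <- function(op) {
  terms <- vapply(op$terms, function(t) {
    p <- parse_factors(t)
    if (!length(p$idx)) return("")
    unparse_factors(rev(p$idx), rev(!p$dag))
  }, character(1), USE.NAMES = FALSE)
  new_fermion_op(terms, Conj(op$coeff))
}

#' Normal ordering under the canonical anticommutation relations
#'
#' Rewrites every product with creation operators to the left (descending
#' mode index) and annihilation operators to the right (ascending index),
#' applying `a_p a_q^ = delta_pq - a_q^ a_p` and dropping repeated
#' identical factors (nilpotency).
#' @param op a `fermion_op`.
#' @export
normal_order <- function(op) {
  out_terms <- character(0); out_coeff <- complex(0)
  work_idx <- lapply(op$terms, parse_factors)
  work <- Map(function(p, c) list(idx = p$idx, dag = p$dag, coeff = c),
              work_idx, as.list(op$coeff))
  while (length(work)) {
    w <- work[[1]]; work <- work[-1]
    idx <- w$idx; dag <- w$dag; cf <- w$coeff
    n <- length(idx)
    swapped <- FALSE
    for (k in seq_len(max(n - 1L, 0L))) {
      a <- k; b <- k + 1L
      # target order: creators (descending index) then annihilators (ascending)
      bad <- (!dag[a] && dag[b]) ||
        (dag[a] && dag[b] && idx[a] < idx[b]) ||
        (!dag[a] && !dag[b] && idx[a] > idx[b])
      if (dag[a] == dag[b] && idx[a] == idx[b]) { swapped <- TRUE; cf <- 0; break }
      if (bad) {
        if (!dag[a] && dag[b] && idx[a] == idx[b]) {
          # a_p a_p^ = 1 - a_p^ a_p
          rem_idx <- idx[-c(a, b)]; rem_dag <- dag[-c(a, b)]
          work <- c(work, list(list(idx = rem_idx, dag = rem_dag, coeff = cf)))
          idx2 <- idx; dag2 <- dag
          idx2[c(a, b)] <- idx[c(b, a)]; dag2[c(a, b)] <- dag[c(b, a)]
          work <- c(work, list(list(idx = idx2, dag = dag2, coeff = -cf)))
        } else {
          idx2 <- idx; dag2 <- dag
          idx2[c(a, b)] <- idx[c(b, a)]; dag2[c(a, b)] <- dag[c(b, a)]
          work <- c(work, list(list(idx = idx2, dag = dag2, coeff = -cf)))
        }
        swapped <- TRUE
        break
      }
    }
    if (!swapped && cf != 0) {
      out_terms <- c(out_terms, unparse_factors(idx, dag))
      out_coeff <- c(out_coeff, cf)
    }
  }
  new_fermion_op(out_terms, out_coeff)
}

# Jordan-Wigner image of a single ladder operator on a fixed register:
# a_p = Z_0...Z_{p-1} (X_p + i Y_p)/2, qubit index = spin-orbital index
jw_ladder <- function(p, dag, n_modes) {
  xm <- bitwShiftL(1L, p)
  zchain <- xm - 1L
  cf <- if (dag) c(0.5 + 0i, 0 - 0.5i) else c(0.5 + 0i, 0 + 0.5i)
  new_pauli_sum(c(xm, xm), c(zchain, bitwOr(zchain, xm)), cf, n_modes,
                aggregate = FALSE)
}

#' Jordan-Wigner transformation
#'
#' Maps a fermionic operator to an N-qubit Pauli sum.  Qubit `q` carries the
#' occupation of spin orbital `q`; the parity (Z) chain acts on qubits below
#' the mode index.  The map is linear, preserves Hermiticity, and is a
#' homomorphism on operator products.
#'
#' @param op a [fermion_op()].
#' @param n_modes number of spin orbitals (= qubits) of the register.
#' @return a [pauli_sum()] on `n_modes` qubits.
#' @export
jordan_wigner <- function(op, n_modes) {
  mx <- fermion_max_mode(op)
  if (mx >= n_modes)
    stop_arg("operator acts on mode ", mx, " but register has ", n_modes)
  acc_x <- integer(0); acc_z <- integer(0); acc_c <- complex(0)
  for (i in seq_along(op$coeff)) {
    p <- parse_factors(op$terms[i])
    cur <- pauli_identity(n_modes, op$coeff[i])
    for (k in seq_along(p$idx))
      cur <- pauli_mult(cur, jw_ladder(p$idx[k], p$dag[k], n_modes))
    acc_x <- c(acc_x, cur$x); acc_z <- c(acc_z, cur$z); acc_c <- c(acc_c, cur$coeff)
  }
  new_pauli_sum(acc_x, acc_z, acc_c, n_modes)
}

#' Total particle-number operator as a Pauli sum
#' @param n_modes number of spin orbitals (= qubits).
#' @export
number_operator <- function(n_modes) {
  # sum_p a_p^ a_p = sum_p (I - Z_p)/2
  new_pauli_sum(c(0L, rep(0L, n_modes)),
                c(0L, bitwShiftL(1L, seq_len(n_modes) - 1L)),
                c(n_modes / 2 + 0i, rep(-0.5 + 0i, n_modes)), n_modes)
}
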