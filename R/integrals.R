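#' Active-space electron integral tables
#'
#' Container for the one- and two-electron integrals (in Hartree) defining a
#' complete-active-space CAS(n_e, n_o) Hamiltonian, plus the core (frozen +
#' nuclear) energy.  The two-electron array is held internally in physicist
#' notation `<pq|rs>`; FCIDUMP files, which store chemist notation `(pq|rs)`,
#' are converted on ingest and egress.
#'
#' @param n_spatial_orbitals number of active spatial orbitals.
#' @param n_electrons number of active electrons (at most `2 * n_o`).
#' @param core_energy scalar core energy in Hartree.
#' @param h1 symmetric `n_o x n_o` one-electron integral matrix.
#' @param h2 rank-4 array of two-electron integrals in the convention named
#'   by `convention`.
#' @param convention `"physicist"` (`<pq|rs>`, default) or `"chemist"`
#'   (`(pq|rs)`, the FCIDUMP layout).
#' @return an object of class `integral_table`.
#' @export
integral_table <- function(n_spatial_orbitals, n_electrons, core_energy = 0,
                           h1, h2, convention = c("physicist", "chemist")) {
  convention <- match.arg(convention)
  n <- as.integer(n_spatial_orbitals)
  ne <- as.integer(n_electrons)
  if (n < 1L) stop_arg("n_spatial_orbitals must be positive")
  if (ne < 0L || ne > 2L * n)
    stop_arg("n_electrons must lie in [0, 2 * n_spatial_orbitals]")
  h1 <- as.matrix(h1)
  stopifnot(all(dim(h1) == n), all(dim(h2) == n))
  if (convention == "chemist") h2 <- chemist_to_physicist(h2)
  tab <- structure(list(n_spatial_orbitals = n, n_electrons = ne,
                        core_energy = as.numeric(core_energy),
                        h1 = h1, h2 = h2),
                   class = "integral_table")
  validate_integral_table(tab)
  tab
}

# physicist <pq|rs> = chemist (pr|qs)
chemist_to_physicist <- function(g) {
  n <- dim(g)[1]
  aperm(g, c(1, 3, 2, 4))
}

physicist_to_chemist <- function(h2) aperm(h2, c(1, 3, 2, 4))

validate_integral_table <- function(tab, tol = 1e-10) {
  if (max(abs(tab$h1 - t(tab$h1))) > tol)
    stop_arg("h1 is not symmetric")
  g <- physicist_to_chemist(tab$h2)
  for (p in list(c(2, 1, 3, 4), c(1, 2, 4, 3), c(3, 4, 1, 2)))
    if (max(abs(g - aperm(g, p))) > tol)
      stop_arg("h2 violates the 8-fold real-orbital permutation symmetry")
  invisible(tab)
}

#' @export
print.integral_table <- function(x, ...) {
  cat(sprintf("<integral_table: CAS(%d,%d), core energy %.8f Ha>\n",
              x$n_electrons, x$n_spatial_orbitals, x$core_energy))
  invisible(x)
}

#' @rdname integral_table
#' @param tab an `integral_table`.
#' @export
n_spin_orbitals <- function(tab) 2L * tab$n_spatial_orbitals

# average a chemist-notation array over its 8 real-orbital permutations
symmetrize_chemist <- function(g) {
  perms <- list(c(1, 2, 3, 4), c(2, 1, 3, 4), c(1, 2, 4, 3), c(2, 1, 4, 3),
                c(3, 4, 1, 2), c(4, 3, 1, 2), c(3, 4, 2, 1), c(4, 3, 2, 1))
  out <- array(0, dim(g))
  for (p in perms) out <- out + aperm(g, p)
  out / 8
}

#' Random symmetric integral tables
#'
#' Draws all integrals from a standard normal and symmetrizes: `h1` is made
#' symmetric and `h2` is averaged over the 8-fold permutation group of real
#' orbitals.  Deterministic for a fixed seed; magnitudes are left unscaled
#' since only the symmetry structure matters for its role as a test system.
#'
#' @inheritParams integral_table
#' @param seed integer seed for the private RNG stream.
#' @export
synthesize_integrals <- function(n_spatial_orbitals, n_electrons, seed) {
  n <- as.integer(n_spatial_orbitals)
  if (n_electrons < 0 || n_electrons > 2L * n)
    stop_arg("n_electrons must lie in [0, 2 * n_spatial_orbitals]")
  with_seed(seed, {
    h1 <- matrix(stats::rnorm(n * n), n, n)
    h1 <- (h1 + t(h1)) / 2
    g <- array(stats::rnorm(n^4), rep(n, 4))
    g <- symmetrize_chemist(g)
    core <- stats::rnorm(1)
    integral_table(n, n_electrons, core, h1, g, convention = "chemist")
  })
}

#' Synthetic pi-electron model integrals for short polyenes
#'
#' Builds a Pariser-Parr-Pople (PPP) pi-electron active space for an
#' `n_sites`-carbon linear polyene at half filling, with the standard
#' parameterization: alternating double/single-bond Hueckel hoppings
#' `t = -2.58 / -2.22` eV on 1.35 / 1.46 Angstrom bonds, on-site
#' repulsion `U = 11.26` eV, and long-range density-density repulsion
#' from the Ohno interpolation `V(r) = U / sqrt(1 + (U r / 14.397)^2)`,
#' with the conventional charge-neutralizing `(n_i - 1)` shifts folded
#' into the one-body diagonal and the core energy.  All values are
#' converted to Hartree, and the table is returned in the Hueckel
#' molecular-orbital basis so the closed-shell reference determinant is
#' meaningful.  `n_sites = 2` gives an ethylene-like CAS(2,2),
#' `n_sites = 4` a butadiene-like CAS(4,4); singlet-triplet and optical
#' gaps come out at realistic polyene scales (~3 and ~5-6 eV).  These are
#' synthetic stand-ins for ab initio active-space integrals, not
#' spectroscopic reproductions.
#'
#' @param n_sites number of carbon pi sites (= spatial orbitals).
#' @param hopping_ev nearest-neighbour hoppings, recycled over bonds in the
#'   alternating double/single pattern of a linear polyene.
#' @param onsite_ev on-site Coulomb repulsion.
#' @param bond_length_angstrom bond lengths, recycled like `hopping_ev`.
#' @export
polyene_pi_integrals <- function(n_sites, hopping_ev = c(-2.58, -2.22),
                                 onsite_ev = 11.26,
                                 bond_length_angstrom = c(1.35, 1.46)) {
  n <- as.integer(n_sites)
  if (n < 2L) stop_arg("need at least 2 sites")
  ha <- 27.211386245988  # eV per Hartree
  tb <- rep_len(hopping_ev, n - 1L)
  rb <- rep_len(bond_length_angstrom, n - 1L)
  pos <- cumsum(c(0, rb))
  r <- abs(outer(pos, pos, "-"))
  V <- onsite_ev / sqrt(1 + (onsite_ev * r / 14.397)^2)  # eV, Ohno
  h1 <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) h1[i, i + 1L] <- h1[i + 1L, i] <- tb[i] / ha
  offsite <- V - diag(diag(V))
  diag(h1) <- -rowSums(offsite) / ha
  core <- sum(offsite[upper.tri(offsite)]) / ha
  g <- array(0, rep(n, 4))
  for (i in seq_len(n)) for (j in seq_len(n)) g[i, i, j, j] <- V[i, j] / ha
  tab <- integral_table(n, n, core, h1, g, convention = "chemist")
  # express in the Hueckel molecular-orbital basis: the site basis has a
  # uniformly half-filled reference determinant, useless as an EOM/UCCSD
  # reference, whereas the h1 eigenbasis gives the standard closed-shell one
  rotate_orbitals(tab, mo_coefficients(h1))
}

# deterministic ascending-energy eigenbasis with sign-fixed columns
mo_coefficients <- function(h1) {
  e <- eigen(h1, symmetric = TRUE)
  C <- e$vectors[, order(e$values), drop = FALSE]
  for (k in seq_len(ncol(C))) {
    j <- which.max(abs(C[, k]))
    if (C[j, k] < 0) C[, k] <- -C[, k]
  }
  C
}

#' Rotate an integral table to a new orbital basis
#'
#' Applies an orthogonal spatial-orbital rotation `C` (columns = new
#' orbitals in terms of old) to the one- and two-electron integrals.
#' @param tab an [integral_table()].
#' @param C orthogonal `n x n` coefficient matrix.
#' @export
rotate_orbitals <- function(tab, C) {
  n <- tab$n_spatial_orbitals
  stopifnot(all(dim(C) == n))
  h1 <- t(C) %*% tab$h1 %*% C
  g <- physicist_to_chemist(tab$h2)
  v <- as.vector(g)
  for (m in 1:4) v <- apply_mode(v, t(C), m, rep(n, 4))
  g <- array(Re(v), rep(n, 4))
  integral_table(n, tab$n_electrons, tab$core_energy, (h1 + t(h1)) / 2, g,
                 convention = "chemist")
}

#' Read and write FCIDUMP integral files
#'
#' `read_fcidump()` parses the plain-text FCIDUMP interchange format
#' (namelist header with `NORB`, `NELEC`, `MS2`; one `value i j k l` record
#' per line, 1-based indices, chemist notation, index 0 padding for
#' one-electron and core records) and populates all permutation-equivalent
#' entries.  Orbital symmetry labels are ignored.
#'
#' @param path file path.
#' @return an [integral_table()].
#' @export
read_fcidump <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr_end <- grep("(&END|/\\s*$|\\$END)", toupper(lines))[1]
  if (is.na(hdr_end)) stop_arg("FCIDUMP parse error: header terminator not found")
  hdr <- paste(lines[seq_len(hdr_end)], collapse = " ")
  get_key <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "\\s*=\\s*-?[0-9]+"), toupper(hdr)))
    if (!length(m)) return(NA_integer_)
    val <- sub(".*=\\s*", "", m)
    if (!grepl("^-?[0-9]+$", val))
      stop_arg("FCIDUMP parse error: non-integer ", key)
    as.integer(val)
  }
  norb <- get_key("NORB"); nelec <- get_key("NELEC")
  if (is.na(norb) || is.na(nelec))
    stop_arg("FCIDUMP parse error: malformed header (NORB/NELEC missing)")
  h1 <- matrix(0, norb, norb)
  g <- array(0, rep(norb, 4))
  core <- 0
  for (ln in seq(hdr_end + 1L, length.out = max(0L, length(lines) - hdr_end))) {
    txt <- trimws(lines[ln])
    if (!nzchar(txt)) next
    f <- strsplit(txt, "\\s+")[[1]]
    if (length(f) != 5L)
      stop_arg("FCIDUMP parse error at line ", ln, ": expected 5 fields")
    val <- suppressWarnings(as.numeric(f[1]))
    ijkl <- suppressWarnings(as.integer(f[2:5]))
    if (is.na(val) || anyNA(ijkl))
      stop_arg("FCIDUMP parse error at line ", ln, ": non-numeric field")
    if (any(ijkl < 0L) || any(ijkl > norb))
      stop_arg("FCIDUMP parse error at line ", ln, ": index out of range")
    i <- ijkl[1]; j <- ijkl[2]; k <- ijkl[3]; l <- ijkl[4]
    if (i == 0L) {
      core <- val
    } else if (k == 0L) {
      if (j == 0L) stop_arg("FCIDUMP parse error at line ", ln,
                            ": one-electron record needs two indices")
      h1[i, j] <- h1[j, i] <- val
    } else {
      for (p in list(c(i, j, k, l), c(j, i, k, l), c(i, j, l, k),
                     c(j, i, l, k), c(k, l, i, j), c(l, k, i, j),
                     c(k, l, j, i), c(l, k, j, i)))
        g[p[1], p[2], p[3], p[4]] <- val
    }
  }
  integral_table(norb, nelec, core, h1, g, convention = "chemist")
}

#' @rdname read_fcidump
#' @param tab an [integral_table()].
#' @param ms2 value written for the MS2 header key.
#' @export
write_fcidump <- function(tab, path, ms2 = 0L) {
  n <- tab$n_spatial_orbitals
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("&FCI NORB=%d,NELEC=%d,MS2=%d,", n, tab$n_electrons, ms2),
               sprintf(" ORBSYM=%s", paste(rep("1,", n), collapse = "")),
               " ISYM=1,", "&END"), con)
  fmt <- function(v, i, j, k, l) sprintf("%23.16E %3d %3d %3d %3d", v, i, j, k, l)
  g <- physicist_to_chemist(tab$h2)
  out <- character(0)
  for (i in seq_len(n)) for (j in seq_len(i))
    for (k in seq_len(i)) for (l in seq_len(k)) {
      if (k == i && l > j) next
      if (g[i, j, k, l] != 0)
        out <- c(out, fmt(g[i, j, k, l], i, j, k, l))
    }
  for (i in seq_len(n)) for (j in seq_len(i))
    if (tab$h1[i, j] != 0) out <- c(out, fmt(tab$h1[i, j], i, j, 0L, 0L))
  out <- c(out, fmt(tab$core_energy, 0L, 0L, 0L, 0L))
  writeLines(out, con)
  invisible(path)
}

#' Second-quantized active-space Hamiltonian
#'
#' Assembles `core + sum h_pq a_p^ a_q + 1/2 sum <pq|rs> a_p^ a_q^ a_s a_r`
#' over spin orbitals, duplicating the spatial integrals across same-spin
#' channels.  Spin orbitals use block spin ordering: spatial orbital `p`
#' with spin alpha is mode `p`, with spin beta mode `p + n_o` (0-based).
#'
#' @param integrals an [integral_table()].
#' @return a [fermion_op()]; Hermitian by construction.
#' @export
build_fermionic_hamiltonian <- function(integrals) {
  n <- integrals$n_spatial_orbitals
  terms <- character(0); coeff <- numeric(0)
  if (integrals$core_energy != 0) {
    terms <- ""
    coeff <- integrals$core_energy
  }
  # one-body: both spin channels
  idx <- which(integrals$h1 != 0, arr.ind = TRUE)
  if (nrow(idx)) {
    for (s in c(0L, n)) {
      terms <- c(terms, paste0(idx[, 1] - 1L + s, "^ ", idx[, 2] - 1L + s))
      coeff <- c(coeff, integrals$h1[idx])
    }
  }
  # two-body: 1/2 sum_{pqrs} <pq|rs> a^_{p,s1} a^_{q,s2} a_{s,s2} a_{r,s1}
  nz <- which(integrals$h2 != 0, arr.ind = TRUE)
  if (nrow(nz)) {
    v <- integrals$h2[nz]
    for (s1 in c(0L, n)) for (s2 in c(0L, n)) {
      P <- nz[, 1] - 1L + s1; Q <- nz[, 2] - 1L + s2
      R <- nz[, 3] - 1L + s1; S <- nz[, 4] - 1L + s2
      keep <- P != Q & R != S  # same-mode double creation/annihilation vanishes
      if (any(keep)) {
        terms <- c(terms, paste0(P[keep], "^ ", Q[keep], "^ ", S[keep], " ", R[keep]))
        coeff <- c(coeff, 0.5 * v[keep])
      }
    }
  }
  fermion_op(terms, coeff)
}

#' Qubit Hamiltonian of an active space
#'
#' Convenience wrapper: [build_fermionic_hamiltonian()] followed by
#' [jordan_wigner()] on `2 * n_o` qubits.
#' @inheritParams build_fermionic_hamiltonian
#' @export
qubit_hamiltonian <- function(integrals)
  jordan_wigner(build_fermionic_hamiltonian(integrals),
                n_spin_orbitals(integrals))

#' Hartree-Fock reference occupations
#'
#' 0-based spin-orbital indices occupied in the closed/open-shell reference
#' determinant under block spin ordering (alpha gets the extra electron for
#' odd counts).
#' @inheritParams build_fermionic_hamiltonian
#' @export
reference_occupations <- function(integrals) {
  n <- integrals$n_spatial_orbitals
  na <- ceiling(integrals$n_electrons / 2)
  nb <- integrals$n_electrons - na
  c(seq_len(na) - 1L, n + seq_len(nb) - 1L)
}
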