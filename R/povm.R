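#' The canonical single-qubit SIC-POVM and its dual frame
#'
#' Effects are `Pi_i = |psi_i><psi_i| / 2` with `|psi_0> = |0>` and
#' `|psi_k>` proportional to `|0> + sqrt(2) exp(i 2 pi (k-1)/3) |1>` for
#' `k = 1, 2, 3`.  The rescaled effects `2 Pi_i` have the symmetric overlap
#' pattern `Tr[(2Pi_i)(2Pi_j)] = (2 delta_ij + 1)/3`.  The dual frame is
#' closed-form, `D_i = 3 (2 Pi_i) - I`, so that any single-qubit operator
#' satisfies `O = sum_i Tr[D_i O] Pi_i`; a numerical frame-superoperator
#' inversion is kept as an independent oracle in the test suite.
#'
#' @return an object of class `sic_povm`: lists `effects` and `duals` of
#'   four 2x2 complex matrices.
#' @export
canonical_sic <- function() {
  kets <- list(c(1, 0) + 0i)
  for (k in 1:3) {
    v <- c(1, sqrt(2) * exp(2i * pi * (k - 1) / 3))
    kets[[k + 1]] <- v / sqrt(sum(Mod(v)^2))
  }
  effects <- lapply(kets, function(v) (v %*% Conj(t(v))) / 2)
  duals <- lapply(effects, function(P) 6 * P - diag(2))
  structure(list(effects = effects, duals = duals), class = "sic_povm")
}

#' @export
print.sic_povm <- function(x, ...) {
  cat("<sic_povm: 4 canonical single-qubit effects>\n")
  invisible(x)
}

pauli_matrices <- function() list(
  I = diag(2) + 0i,
  X = matrix(c(0, 1, 1, 0), 2) + 0i,
  Y = matrix(c(0, 1i, -1i, 0), 2),
  Z = matrix(c(1, 0, 0, -1), 2) + 0i)

# cached 4x4 single-qubit transfer matrices for the tensorized transforms;
# mode index order for Pauli letters is I, X, Y, Z, for outcomes 0..3,
# and for density "rc" pairs r + 2c (row bit fastest)
povm_transfer <- function(povm = canonical_sic()) {
  key <- "transfer_canonical"
  cached <- .qeom_env[[key]]
  if (!is.null(cached)) return(cached)
  sig <- pauli_matrices()
  B <- matrix(0 + 0i, 4, 4)     # outcome <- rc : p_m = sum rho[r,c] Pi_m[c,r]
  Tm <- matrix(0 + 0i, 4, 4)    # letter x outcome : Tr[D_m sigma_L]
  C <- matrix(0 + 0i, 4, 4)     # rc <- letter : sigma_L[r,c] / 2
  E <- matrix(0 + 0i, 4, 4)     # letter <- rc : Tr[rho sigma_L]
  for (m in 1:4) for (r in 0:1) for (c in 0:1)
    B[m, 1 + r + 2 * c] <- povm$effects[[m]][c + 1, r + 1]
  for (L in 1:4) for (m in 1:4)
    Tm[L, m] <- sum(diag(povm$duals[[m]] %*% sig[[L]]))
  for (L in 1:4) for (r in 0:1) for (c in 0:1) {
    C[1 + r + 2 * c, L] <- sig[[L]][r + 1, c + 1] / 2
    E[L, 1 + r + 2 * c] <- sig[[L]][c + 1, r + 1]
  }
  out <- list(B = B, T = Tm, C = C, E = E)
  .qeom_env[[key]] <- out
  out
}

# flatten a density matrix into the qubit-interleaved (r_q, c_q) mode order
rho_to_modes <- function(rho, nq) {
  dim(rho) <- rep(2L, 2L * nq)
  as.vector(aperm(rho, as.vector(rbind(seq_len(nq), nq + seq_len(nq)))))
}

modes_to_rho <- function(v, nq) {
  a <- array(v, rep(2L, 2L * nq))
  a <- aperm(a, order(as.vector(rbind(seq_len(nq), nq + seq_len(nq)))))
  dim(a) <- c(2^nq, 2^nq)
  a
}

state_nq <- function(state) {
  nq <- as.integer(round(log2(length(state))))
  if (2^nq != length(state)) stop_arg("state length is not a power of 2")
  nq
}

check_normalized <- function(state, tol = 1e-8) {
  if (abs(sum(Mod(state)^2) - 1) > tol)
    stop_arg("state vector is not normalized")
}

ENUM_QUBIT_CAP <- 8L

#' Outcome distribution of a product SIC-POVM measurement
#'
#' Returns `p_m = <state| kron_q Pi_{m_q} |state>` over all `4^N` outcome
#' strings, with the qubit-0 outcome as the fastest-varying digit of the
#' outcome index.  Full enumeration is used for at most 8 qubits; larger
#' registers are sampled by sequential conditioning instead
#' (see [sample_outcomes()]).
#'
#' @param state normalized complex state vector.
#' @param povm a [canonical_sic()] POVM.
#' @return numeric probability vector of length `4^N` summing to 1.
#' @export
outcome_distribution <- function(state, povm = canonical_sic()) {
  nq <- state_nq(state)
  check_normalized(state)
  if (nq > ENUM_QUBIT_CAP)
    stop_arg("full outcome enumeration capped at ", ENUM_QUBIT_CAP, " qubits")
  tr <- povm_transfer(povm)
  v <- rho_to_modes(outer(state, Conj(state)), nq)
  p <- Re(apply_all_modes4(v, tr$B, nq))
  pmax(p, 0)
}

decode_outcomes <- function(key, nq) {
  out <- matrix(0L, length(key), nq)
  k <- key
  for (q in seq_len(nq)) {
    out[, q] <- k %% 4L
    k <- k %/% 4L
  }
  out
}

encode_outcomes <- function(outcomes) {
  key <- rep(0, nrow(outcomes))
  for (q in rev(seq_len(ncol(outcomes)))) key <- key * 4 + outcomes[, q]
  key
}

#' Simulate SIC-POVM measurement shots
#'
#' Draws `S` i.i.d. outcome strings from the product SIC-POVM distribution
#' of `state`.  Registers up to 8 qubits use the enumerated distribution;
#' larger registers are sampled exactly by the chain rule, conditioning one
#' qubit at a time on the earlier outcomes (identical distribution, no
#' `4^N` table).  One sample set is intended to be reused for every
#' observable estimated on the same state.
#'
#' @inheritParams outcome_distribution
#' @param S number of shots (at least 1).
#' @param seed integer seed for the private RNG stream.
#' @param state_id provenance tag stored with the samples.
#' @return an object of class `sample_set`: integer outcome matrix
#'   (`S x N`, entries 0..3) plus `S`, `seed`, `state_id`.
#' @export
sample_outcomes <- function(state, povm = canonical_sic(), S, seed,
                            state_id = "state") {
  if (S < 1L) stop_arg("S must be at least 1")
  nq <- state_nq(state)
  check_normalized(state)
  outcomes <- with_seed(seed, {
    if (nq <= ENUM_QUBIT_CAP) {
      p <- outcome_distribution(state, povm)
      decode_outcomes(sample.int(length(p), S, replace = TRUE, prob = p) - 1L, nq)
    } else {
      chain_sample(state, povm, S, nq)
    }
  })
  structure(list(outcomes = outcomes, S = as.integer(S),
                 seed = as.integer(seed), state_id = state_id,
                 n_qubits = nq),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set: %d shots on %d qubits, seed %d, state '%s'>\n",
              x$S, x$n_qubits, x$seed, x$state_id))
  invisible(x)
}

# recursive chain-rule sampler: condition the highest remaining qubit,
# split the shot count multinomially, recurse on the collapsed branches
chain_sample <- function(psi, povm, S, nq) {
  if (nq == 0L || S == 0L) return(matrix(0L, S, nq))
  half <- 2^(nq - 1L)
  lo <- psi[seq_len(half)]; hi <- psi[half + seq_len(half)]
  branches <- vector("list", 4)
  p <- numeric(4)
  for (m in 1:4) {
    P <- povm$effects[[m]]
    # (<psi_m| on the top qubit) acting from the effect decomposition:
    # Pi = |v><v|/2 with v recovered from the effect's columns
    ev <- eigen(P, symmetric = TRUE)
    v <- ev$vectors[, 1] * sqrt(ev$values[1])
    b <- Conj(v[1]) * lo + Conj(v[2]) * hi
    branches[[m]] <- b
    p[m] <- sum(Mod(b)^2)
  }
  counts <- drop(stats::rmultinom(1, S, p))
  rows <- vector("list", 4)
  for (m in 1:4) {
    if (counts[m] == 0L) { rows[[m]] <- matrix(0L, 0, nq); next }
    sub <- branches[[m]] / sqrt(p[m])
    lower <- chain_sample(sub, povm, counts[m], nq - 1L)
    rows[[m]] <- cbind(lower, rep(m - 1L, counts[m]))
  }
  out <- do.call(rbind, rows)
  # shuffle so shots are exchangeable rather than grouped by branch
  out[sample.int(nrow(out)), , drop = FALSE]
}

# flat index (0-based) of each Pauli string of ps in I,X,Y,Z mode order
pauli_flat_index <- function(ps) {
  idx <- rep(0, length(ps$x))
  lut <- c(0, 1, 3, 2)  # (x + 2z) -> letter position I,X,Y,Z
  for (q in seq_len(ps$n_qubits)) {
    xb <- bitwAnd(bitwShiftR(ps$x, q - 1L), 1L)
    zb <- bitwAnd(bitwShiftR(ps$z, q - 1L), 1L)
    idx <- idx + lut[1L + xb + 2L * zb] * 4^(q - 1L)
  }
  idx
}

#' Dual-frame weights of an observable for a sample set
#'
#' For each measured outcome string `m`, computes the complex weight
#' `omega_m = sum_P coeff_P prod_q Tr[D_{m_q} P_q]` whose sample mean is an
#' unbiased estimator of `<O>`.  Identity letters contribute a factor 1.
#'
#' @param O a [pauli_sum()] on the sampled register.
#' @param povm the POVM that generated the samples.
#' @param samples a [sample_outcomes()] result.
#' @return complex vector of length `S`.
#' @export
observable_weights <- function(O, povm = canonical_sic(), samples) {
  if (O$n_qubits != samples$n_qubits)
    stop_arg("observable and samples act on different registers")
  tr <- povm_transfer(povm)
  Tm <- tr$T  # letter x outcome
  lut <- c(1L, 2L, 4L, 3L)  # (x + 2z) -> row of Tm (I,X,Y,Z)
  w <- complex(samples$S)
  for (t in seq_along(O$coeff)) {
    wt <- rep(O$coeff[t], samples$S)
    for (q in seq_len(O$n_qubits)) {
      xb <- bitwAnd(bitwShiftR(O$x[t], q - 1L), 1L)
      zb <- bitwAnd(bitwShiftR(O$z[t], q - 1L), 1L)
      if (xb == 0L && zb == 0L) next
      L <- lut[1L + xb + 2L * zb]
      wt <- wt * Tm[L, samples$outcomes[, q] + 1L]
    }
    w <- w + wt
  }
  w
}

#' Monte Carlo estimate and standard error from dual-frame weights
#'
#' The estimator is the sample mean of the weights; its standard error is
#' `sqrt((<w^2> - <w>^2) / S)` from sample moments, reported separately for
#' the real and imaginary parts.  With fewer than 2 shots the error is
#' undefined (`NA`).
#'
#' @param weights complex weight vector from [observable_weights()].
#' @return a list with `estimate`, `std_error_real`, `std_error_imag`, `S`.
#' @export
estimate_expectation <- function(weights) {
  S <- length(weights)
  est <- mean(weights)
  if (S < 2L) {
    se_r <- NA_real_; se_i <- NA_real_
  } else {
    vr <- mean(Re(weights)^2) - mean(Re(weights))^2
    vi <- mean(Im(weights)^2) - mean(Im(weights))^2
    se_r <- sqrt(max(vr, 0) / S)
    se_i <- sqrt(max(vi, 0) / S)
  }
  list(estimate = est, std_error_real = se_r, std_error_imag = se_i, S = S)
}

#' Per-Pauli-string estimates and the frame-reconstructed density operator
#'
#' `string_estimates()` maps the empirical outcome-frequency tensor through
#' the per-qubit dual overlap matrices, returning in one pass the estimated
#' expectation of every Pauli string (a `4^N` vector in I,X,Y,Z mode order,
#' qubit 0 fastest).  `shadow_density()` assembles them into the operator
#' `rho_hat = sum_P est_P P / 2^N`, the linear-inversion ("shadow")
#' reconstruction: `Tr[rho_hat O]` equals the sample mean of the
#' dual-frame weights of `O` exactly, for every observable, so one sample
#' set serves all observables.  `rho_hat` is Hermitian and unit trace but
#' not necessarily positive.
#'
#' @param samples a [sample_outcomes()] result (at most 8 qubits).
#' @param povm the POVM that generated the samples.
#' @export
string_estimates <- function(samples, povm = canonical_sic()) {
  nq <- samples$n_qubits
  if (nq > ENUM_QUBIT_CAP)
    stop_arg("string_estimates requires at most ", ENUM_QUBIT_CAP, " qubits")
  key <- encode_outcomes(samples$outcomes)
  f <- tabulate(key + 1L, nbins = 4^nq) / samples$S
  tr <- povm_transfer(povm)
  Re(apply_all_modes4(f + 0i, tr$T, nq))
}

#' @rdname string_estimates
#' @param estimates optionally, a precomputed [string_estimates()] vector.
#' @export
shadow_density <- function(samples, povm = canonical_sic(),
                           estimates = NULL) {
  nq <- if (!is.null(samples)) samples$n_qubits
        else as.integer(round(log(length(estimates), 4)))
  if (is.null(estimates)) estimates <- string_estimates(samples, povm)
  tr <- povm_transfer(povm)
  v <- apply_all_modes4(estimates + 0i, tr$C, nq)
  modes_to_rho(v, nq)
}

#' Expectation of a Pauli sum against a density operator
#' @param ps a [pauli_sum()].
#' @param rho dense density (or any) matrix of matching dimension.
#' @export
pauli_expect_rho <- function(ps, rho) {
  d <- 2^ps$n_qubits
  if (!all(dim(rho) == d)) stop_arg("dimension mismatch")
  b <- 0:(d - 1L)
  acc <- 0 + 0i
  for (t in seq_along(ps$coeff)) {
    x <- ps$x[t]; z <- ps$z[t]
    ph <- i_power(popcount(bitwAnd(x, z))) *
      (1 - 2 * (popcount(bitwAnd(z, b)) %% 2L))
    acc <- acc + ps$coeff[t] * sum(rho[cbind(b + 1L, bitwXor(b, x) + 1L)] * ph)
  }
  acc
}

#' Persist and restore sample sets as plain CSV
#'
#' Columns: `shot` index plus one `q<k>` outcome column per qubit;
#' provenance (`S`, `seed`, `state_id`) travels in a header comment line.
#' @param samples a [sample_outcomes()] result.
#' @param path CSV file path.
#' @export
write_sample_set <- function(samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_set S=%d seed=%d state_id=%s",
                     samples$S, samples$seed, samples$state_id), con)
  df <- as.data.frame(samples$outcomes)
  names(df) <- paste0("q", seq_len(ncol(df)) - 1L)
  df <- cbind(shot = seq_len(nrow(df)), df)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_set
#' @export
read_sample_set <- function(path) {
  hdr <- readLines(path, n = 1L)
  g <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    sub(".*=", "", m)
  }
  df <- utils::read.csv(path, comment.char = "#")
  outcomes <- as.matrix(df[, -1, drop = FALSE])
  dimnames(outcomes) <- NULL
  structure(list(outcomes = outcomes, S = nrow(outcomes),
                 seed = as.integer(g("seed")),
                 state_id = g("state_id"),
                 n_qubits = ncol(outcomes)),
            class = "sample_set")
}
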