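## internal helpers shared across modules

.qeom_env <- new.env(parent = emptyenv())

# popcount for non-negative integers < 2^24 (12-bit table applied twice);
# qubit registers are capped at 12 so all bit masks fit comfortably
popcount <- function(v) {
  tab <- .qeom_env$poptab
  if (is.null(tab)) {
    tab <- integer(4096L)
    for (b in 0:11) tab <- tab + bitwAnd(bitwShiftR(0:4095, b), 1L)
    .qeom_env$poptab <- tab
  }
  tab[bitwAnd(v, 4095L) + 1L] + tab[bitwAnd(bitwShiftR(v, 12L), 4095L) + 1L]
}

i_power <- function(e) {
  # i^e for integer exponents, exact
  c(1 + 0i, 0 + 1i, -1 + 0i, 0 - 1i)[(e %% 4L) + 1L]
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

# run expr with a private RNG stream seeded by `seed`, restoring global state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# apply a (k x d) matrix along one mode of a flat vector seen as a
# dims-shaped array; returns the flat vector of the transformed array
apply_mode <- function(v, M, mode, dims) {
  d1 <- prod(dims[seq_len(mode - 1L)])
  d2 <- dims[mode]
  d3 <- length(v) / (d1 * d2)
  a <- array(v, c(d1, d2, d3))
  a <- aperm(a, c(2L, 1L, 3L))
  dim(a) <- c(d2, d1 * d3)
  r <- M %*% a
  dim(r) <- c(nrow(M), d1, d3)
  as.vector(aperm(r, c(2L, 1L, 3L)))
}

# apply the same 4x4 matrix along every one of n modes of a 4^n vector
apply_all_modes4 <- function(v, M, n) {
  for (q in seq_len(n)) v <- apply_mode(v, M, q, rep(4L, n))
  v
}
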