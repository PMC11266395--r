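# Pauli-operator algebra in the symplectic (x, z) bitmask representation.
# A term c * X^x Z^z is stored as (x, z, c) with x, z integer bitmasks over
# qubits (qubit j = bit j, little-endian) and c complex. The standard letter
# Y corresponds to both bits set: Y = i X Z, so a term with nY Y-letters has
# standard-notation coefficient c * (-i)^nY.

# evaluate expr under a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

pauli_zero <- function(n_qubits) {
  list(x = integer(0), z = integer(0), c = complex(0), n = as.integer(n_qubits))
}

pauli_term <- function(n_qubits, x, z, c) {
  list(x = as.integer(x), z = as.integer(z), c = as.complex(c),
       n = as.integer(n_qubits))
}

pauli_identity <- function(n_qubits, c = 1) pauli_term(n_qubits, 0L, 0L, c)

# combine duplicate strings; drop terms below tol
pauli_simplify <- function(op, tol = 0) {
  if (length(op$c) == 0) return(op)
  key <- paste(op$x, op$z)
  cs <- rowsum(cbind(Re(op$c), Im(op$c)), key, reorder = FALSE)
  ux <- op$x[!duplicated(key)]
  uz <- op$z[!duplicated(key)]
  c2 <- complex(real = cs[, 1], imaginary = cs[, 2])
  keep <- Mod(c2) > tol
  list(x = ux[keep], z = uz[keep], c = c2[keep], n = op$n)
}

pauli_add <- function(a, b, simplify = TRUE) {
  op <- list(x = c(a$x, b$x), z = c(a$z, b$z), c = c(a$c, b$c), n = a$n)
  if (simplify) pauli_simplify(op) else op
}

pauli_scale <- function(a, s) { a$c <- a$c * s; a }

.popcount <- local({
  tbl <- integer(65536)
  for (i in 0:15) tbl[bitwShiftL(1L, i) + 1L] <- 1L
  # build by dynamic programming
  function(v) {
    r <- integer(length(v))
    x <- as.integer(v)
    while (any(x > 0)) {
      r <- r + x %% 2L
      x <- x %/% 2L
    }
    r
  }
})

# product of sums: outer expansion with phase (-1)^{|z_a & x_b|}
pauli_mult <- function(a, b, simplify = TRUE) {
  na <- length(a$c); nb <- length(b$c)
  if (na == 0 || nb == 0) return(pauli_zero(a$n))
  ia <- rep(seq_len(na), each = nb)
  ib <- rep(seq_len(nb), times = na)
  sgn <- (-1)^.popcount(bitwAnd(a$z[ia], b$x[ib]))
  op <- list(x = bitwXor(a$x[ia], b$x[ib]),
             z = bitwXor(a$z[ia], b$z[ib]),
             c = a$c[ia] * b$c[ib] * sgn, n = a$n)
  if (simplify) pauli_simplify(op) else op
}

# letters of a term as a string over I, X, Y, Z (qubit 0 first)
pauli_letters <- function(x, z, n) {
  lets <- character(n)
  for (j in seq_len(n)) {
    bx <- bitwAnd(x, bitwShiftL(1L, j - 1L)) > 0
    bz <- bitwAnd(z, bitwShiftL(1L, j - 1L)) > 0
    lets[j] <- if (bx && bz) "Y" else if (bx) "X" else if (bz) "Z" else "I"
  }
  paste(lets, collapse = "")
}

# standard-notation coefficients: multiply by (-i)^{#Y}
pauli_std_coeff <- function(op) {
  nY <- .popcount(bitwAnd(op$x, op$z))
  op$c * (-1i)^nY
}

# dense matrix over the 2^n computational basis (bit j of the index = qubit j)
pauli_matrix <- function(op) {
  n <- op$n
  dim2 <- 2^n
  M <- matrix(0 + 0i, dim2, dim2)
  b <- 0:(dim2 - 1)
  for (t in seq_along(op$c)) {
    sgn <- (-1)^.popcount(bitwAnd(b, op$z[t]))
    rows <- bitwXor(b, op$x[t]) + 1L
    M[cbind(rows, b + 1L)] <- M[cbind(rows, b + 1L)] + op$c[t] * sgn
  }
  M
}

# apply operator to a state vector (complex, length 2^n) without forming the matrix
pauli_apply <- function(op, psi) {
  n2 <- length(psi)
  b <- 0:(n2 - 1)
  out <- complex(n2)
  for (t in seq_along(op$c)) {
    sgn <- (-1)^.popcount(bitwAnd(b, op$z[t]))
    out[bitwXor(b, op$x[t]) + 1L] <- out[bitwXor(b, op$x[t]) + 1L] +
      op$c[t] * sgn * psi
  }
  out
}

# <psi|Op|psi>
pauli_expect <- function(op, psi) {
  sum(Conj(psi) * pauli_apply(op, psi))
}
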