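# Independent oracles built from explicit numeric matrices -- deliberately a
# different code path from the package's symbolic Pauli algebra and
# determinant CI.

# fermionic ladder operators as dense matrices over the occupation basis of
# n_so spin-orbital modes (mode j = bit j of the basis index), built by
# Kronecker products with explicit sign strings
oracle_ladder <- function(n_so) {
  a1 <- matrix(c(0, 0, 1, 0), 2, 2)   # |0><1| with basis order (|0>, |1>)
  Zm <- diag(c(1, -1))
  I2 <- diag(2)
  ops <- vector("list", n_so)
  for (j in seq_len(n_so)) {
    m <- matrix(1, 1, 1)
    for (k in seq_len(n_so)) {
      # kron() puts the FIRST factor on the most significant bits; build so
      # that mode k corresponds to bit k-1 (least significant first)
      fac <- if (k < j) Zm else if (k == j) a1 else I2
      m <- fac %x% m
    }
    ops[[j]] <- m
  }
  ops
}

# dense many-body matrix of an active_hamiltonian over all 4^n_orb occupation
# states (blocked spins: modes 1..n alpha, n+1..2n beta)
oracle_fermion_matrix <- function(ah) {
  n <- ah$n_active_orb
  nso <- 2L * n
  a <- oracle_ladder(nso)
  ad <- lapply(a, t)
  dim2 <- 2^nso
  H <- matrix(0, dim2, dim2)
  for (p in seq_len(n)) for (q in seq_len(n)) {
    hv <- ah$h_eff[p, q]
    if (abs(hv) < 1e-14) next
    for (sg in c(0L, n))
      H <- H + hv * ad[[p + sg]] %*% a[[q + sg]]
  }
  for (p in seq_len(n)) for (q in seq_len(n)) for (r in seq_len(n)) for (s in seq_len(n)) {
    g <- ah$eri_active[p, s, q, r]
    if (abs(g) < 1e-14) next
    for (sg1 in c(0L, n)) for (sg2 in c(0L, n)) {
      pp <- p + sg1; ss <- s + sg1; qq <- q + sg2; rr <- r + sg2
      if (pp == qq || rr == ss) next
      H <- H + 0.5 * g * ad[[pp]] %*% ad[[qq]] %*% a[[rr]] %*% a[[ss]]
    }
  }
  H
}

# occupation of each mode for every basis index of n_so modes
oracle_occupations <- function(n_so) {
  b <- 0:(2^n_so - 1)
  sapply(seq_len(n_so), function(j) bitwAnd(b, bitwShiftL(1L, j - 1L)) > 0)
}

# standard geometries
h2_geom <- function(r = 0.74) geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, r)))
water_geom <- function(jitter = 0, seed = 1) {
  xyz <- rbind(c(0, 0, 0.1173), c(0, 0.7572, -0.4692), c(0, -0.7572, -0.4692))
  if (jitter > 0) xyz <- xyz + .with_jitter(seed, dim(xyz), jitter)
  geometry(c("O", "H", "H"), xyz)
}
.with_jitter <- function(seed, d, amp) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  out <- matrix(rnorm(prod(d), 0, amp), d[1], d[2])
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out
}

# 5-point central finite difference of the CASCI energy along one coordinate
fd_casci_force <- function(geom, basis, spec_fun, atom, dim, h = 1e-3) {
  ener <- function(delta) {
    xyz <- geom$coords
    xyz[atom, dim] <- xyz[atom, dim] + delta * 0.529177210903
    ints <- mol_integrals(geometry(geom$symbols, xyz), basis)
    casci(fold_active_space(ints, spec_fun(ints)))$energy
  }
  -(-ener(2 * h) + 8 * ener(h) - 8 * ener(-h) + ener(-2 * h)) / (12 * h)
}
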