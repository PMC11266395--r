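# FCIDUMP (Molpro dialect) reading and writing. Values are chemists'-order
# integrals (ij|kl); the in-memory tensor uses the same Mulliken convention,
# so the mapping is a direct index copy with 8-fold symmetry completion.

#' Write integrals to an FCIDUMP file
#'
#' Accepts either a full-space [mol_integrals()] object (core energy =
#' nuclear repulsion) or an `active_hamiltonian` (core energy = frozen-core
#' mean field + nuclear repulsion).
#'
#' @param x `mol_integrals` or `active_hamiltonian`.
#' @param path output file.
#' @param tol drop integrals below this magnitude.
#' @export
write_fcidump <- function(x, path, tol = 1e-14) {
  if (inherits(x, "mol_integrals")) {
    n <- x$n_orb; ne <- x$n_elec; h <- x$h_core; g <- x$eri; e0 <- x$e_nuc
  } else if (inherits(x, "active_hamiltonian")) {
    n <- x$n_active_orb; ne <- x$n_active_elec; h <- x$h_eff
    g <- x$eri_active; e0 <- x$e_core
  } else stop("cannot write FCIDUMP for class ", paste(class(x), collapse = "/"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(" &FCI NORB=%d,NELEC=%d,MS2=0,", n, ne), con)
  writeLines(sprintf("  ORBSYM=%s", paste(rep("1,", n), collapse = "")), con)
  writeLines("  ISYM=1,", con)
  writeLines(" &END", con)
  fmt <- " %23.16e %4d %4d %4d %4d"
  for (i in seq_len(n)) for (j in seq_len(i))
    for (k in seq_len(i)) for (l in seq_len(k)) {
      if (k == i && l > j) next
      v <- g[i, j, k, l]
      if (abs(v) > tol) writeLines(sprintf(fmt, v, i, j, k, l), con)
    }
  for (i in seq_len(n)) for (j in seq_len(i))
    if (abs(h[i, j]) > tol) writeLines(sprintf(fmt, h[i, j], i, j, 0, 0), con)
  writeLines(sprintf(fmt, e0, 0, 0, 0, 0), con)
  invisible(path)
}

#' Read an FCIDUMP file into an active-space Hamiltonian
#'
#' @param path FCIDUMP file.
#' @return An `active_hamiltonian` (full 8-fold symmetry restored).
#' @export
read_fcidump <- function(path) {
  lines <- readLines(path)
  hdr_end <- grep("&END|/", lines)[1]
  hdr <- paste(lines[seq_len(hdr_end)], collapse = " ")
  n <- as.integer(sub(".*NORB\\s*=\\s*(\\d+).*", "\\1", hdr))
  ne <- as.integer(sub(".*NELEC\\s*=\\s*(\\d+).*", "\\1", hdr))
  h <- matrix(0, n, n)
  g <- array(0, c(n, n, n, n))
  e0 <- 0
  for (ln in lines[-seq_len(hdr_end)]) {
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    v <- as.numeric(parts[1])
    ij <- as.integer(parts[2:5])
    i <- ij[1]; j <- ij[2]; k <- ij[3]; l <- ij[4]
    if (i == 0) e0 <- v
    else if (k == 0) { h[i, j] <- v; h[j, i] <- v }
    else {
      for (idx in list(c(i, j, k, l), c(j, i, k, l), c(i, j, l, k), c(j, i, l, k),
                       c(k, l, i, j), c(l, k, i, j), c(k, l, j, i), c(l, k, j, i)))
        g[idx[1], idx[2], idx[3], idx[4]] <- v
    }
  }
  active_hamiltonian(h, g, e0, ne)
}
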