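# Molecular geometries: element symbols plus Cartesian coordinates in Angstrom.

#' Create a molecular geometry
#'
#' @param symbols character vector of element symbols.
#' @param coords numeric matrix (n_atom x 3) of Cartesian coordinates in
#'   Angstrom.
#' @return An object of class `mol_geometry`.
#' @examples
#' h2 <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
#' @export
geometry <- function(symbols, coords) {
  coords <- matrix(as.numeric(coords), nrow = length(symbols), ncol = 3)
  if (length(symbols) == 0L) stop("geometry must contain at least one atom")
  element_Z(symbols)  # validates symbols
  structure(list(symbols = as.character(symbols), coords = coords),
            class = "mol_geometry")
}

#' @export
print.mol_geometry <- function(x, ...) {
  cat(sprintf("Molecular geometry: %d atoms (%s)\n", length(x$symbols),
              paste(x$symbols, collapse = " ")))
  invisible(x)
}

#' Read and write XYZ geometry files
#'
#' Standard XYZ format: atom count, comment line, then `symbol x y z` rows in
#' Angstrom.
#'
#' @param path file path.
#' @param geom a [geometry()] object (for writing).
#' @param comment comment line for the second row.
#' @return `read_xyz` returns a `mol_geometry`; `write_xyz` returns `path`
#'   invisibly.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  symbols <- vapply(rows, `[[`, "", 1L)
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  geometry(symbols, coords)
}

#' @rdname read_xyz
#' @export
write_xyz <- function(geom, path, comment = "") {
  lines <- c(as.character(length(geom$symbols)), comment,
             sprintf("%-2s %18.10f %18.10f %18.10f", geom$symbols,
                     geom$coords[, 1], geom$coords[, 2], geom$coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}

# coordinates in Bohr as used by the integral engine
coords_bohr <- function(geom) geom$coords / BOHR_ANGSTROM
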