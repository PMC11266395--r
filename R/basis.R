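# Gaussian basis sets. Exponents and contraction coefficients are the
# standard published STO-3G and 6-31G parameter sets; sp shells are stored as
# separate s and p shells sharing exponents. Coefficients below are the raw
# published values; primitive and contracted normalization is applied at
# shell-list construction time.

.sto3g_c1s <- c(0.1543289673, 0.5353281423, 0.4446345422)
.sto3g_c2s <- c(-0.09996722919, 0.3995128261, 0.7001154689)
.sto3g_c2p <- c(0.1559162750, 0.6076837186, 0.3919573931)
.sto3g_c3s <- c(-0.2196203690, 0.2255954336, 0.9003984260)
.sto3g_c3p <- c(0.01058760429, 0.5951670053, 0.4620010120)

.basis_library <- list(
  "sto-3g" = list(
    H = list(list(l = 0, exps = c(3.425250914, 0.6239137298, 0.1688554040),
                  coefs = .sto3g_c1s)),
    He = list(list(l = 0, exps = c(6.362421394, 1.158922999, 0.3136497915),
                   coefs = .sto3g_c1s)),
    C = list(list(l = 0, exps = c(71.61683735, 13.04509632, 3.530512160),
                  coefs = .sto3g_c1s),
             list(l = 0, exps = c(2.941249355, 0.6834830964, 0.2222899159),
                  coefs = .sto3g_c2s),
             list(l = 1, exps = c(2.941249355, 0.6834830964, 0.2222899159),
                  coefs = .sto3g_c2p)),
    N = list(list(l = 0, exps = c(99.10616896, 18.05231239, 4.885660238),
                  coefs = .sto3g_c1s),
             list(l = 0, exps = c(3.780455879, 0.8784966449, 0.2857143744),
                  coefs = .sto3g_c2s),
             list(l = 1, exps = c(3.780455879, 0.8784966449, 0.2857143744),
                  coefs = .sto3g_c2p)),
    O = list(list(l = 0, exps = c(130.7093214, 23.80886605, 6.443608313),
                  coefs = .sto3g_c1s),
             list(l = 0, exps = c(5.033151319, 1.169596125, 0.3803889600),
                  coefs = .sto3g_c2s),
             list(l = 1, exps = c(5.033151319, 1.169596125, 0.3803889600),
                  coefs = .sto3g_c2p)),
    S = list(list(l = 0, exps = c(533.1257359, 97.10951830, 26.28162542),
                  coefs = .sto3g_c1s),
             list(l = 0, exps = c(33.32975173, 7.745117521, 2.018662926),
                  coefs = .sto3g_c2s),
             list(l = 1, exps = c(33.32975173, 7.745117521, 2.018662926),
                  coefs = .sto3g_c2p),
             list(l = 0, exps = c(2.029194274, 0.5661400518, 0.2215833792),
                  coefs = .sto3g_c3s),
             list(l = 1, exps = c(2.029194274, 0.5661400518, 0.2215833792),
                  coefs = .sto3g_c3p))
  ),
  "6-31g" = list(
    H = list(list(l = 0, exps = c(18.73113696, 2.825394365, 0.6401216923),
                  coefs = c(0.03349460434, 0.2347269535, 0.8137573261)),
             list(l = 0, exps = 0.1612777588, coefs = 1.0)),
    C = list(list(l = 0,
                  exps = c(3047.524880, 457.3695180, 103.9486850,
                           29.21015530, 9.286662960, 3.163926960),
                  coefs = c(0.001834737132, 0.01403732281, 0.06884262226,
                            0.2321844432, 0.4679413484, 0.3623119853)),
             list(l = 0, exps = c(7.868272350, 1.881288540, 0.5442492580),
                  coefs = c(-0.1193324198, -0.1608541517, 1.143456438)),
             list(l = 1, exps = c(7.868272350, 1.881288540, 0.5442492580),
                  coefs = c(0.06899906659, 0.3164239610, 0.7443082909)),
             list(l = 0, exps = 0.1687144782, coefs = 1.0),
             list(l = 1, exps = 0.1687144782, coefs = 1.0)),
    O = list(list(l = 0,
                  exps = c(5484.671660, 825.2349460, 188.0469580,
                           52.96450000, 16.89757040, 5.799635340),
                  coefs = c(0.001831074430, 0.01395017220, 0.06844507810,
                            0.2327143360, 0.4701928980, 0.3585208530)),
             list(l = 0, exps = c(15.53961625, 3.599933586, 1.013761750),
                  coefs = c(-0.1107775495, -0.1480262627, 1.130767015)),
             list(l = 1, exps = c(15.53961625, 3.599933586, 1.013761750),
                  coefs = c(0.07087426823, 0.3397528391, 0.7271585773)),
             list(l = 0, exps = 0.2700058226, coefs = 1.0),
             list(l = 1, exps = 0.2700058226, coefs = 1.0))
  )
)

# double factorial (2k-1)!! with (-1)!! = 1
.dfact <- function(k) if (k <= 0) 1 else prod(seq(1, 2 * k - 1, by = 2))

# primitive normalization for Cartesian (l,0,0)
.prim_norm <- function(a, l) {
  (2 * a / pi)^0.75 * (2 * sqrt(a))^l / sqrt(.dfact(l))
}

#' Build the contracted-shell list for a molecule
#'
#' Expands the per-element basis definitions into a flat shell list with
#' normalized contraction coefficients, ready for the integral engine.
#'
#' @param symbols element symbols.
#' @param basis basis-set name (`"sto-3g"` or `"6-31g"`).
#' @return list with vectors `l`, `atom` (0-based), lists `exps`, `coefs`,
#'   and `nbf`, the total basis-function count.
#' @keywords internal
build_shells <- function(symbols, basis = "sto-3g") {
  basis <- tolower(basis)
  lib <- .basis_library[[basis]]
  if (is.null(lib)) stop("unknown basis set: ", basis)
  l <- integer(0); atom <- integer(0); exps <- list(); coefs <- list()
  for (i in seq_along(symbols)) {
    eldef <- lib[[symbols[i]]]
    if (is.null(eldef))
      stop("basis ", basis, " not available for element ", symbols[i])
    for (shell in eldef) {
      a <- shell$exps
      c0 <- shell$coefs * vapply(a, .prim_norm, 0, l = shell$l)
      # contracted self-overlap for (l,0,0)
      p <- outer(a, a, "+")
      s <- (pi / p)^1.5 * (.dfact(shell$l) / (2 * p)^shell$l)
      nrm <- sqrt(drop(crossprod(c0, s %*% c0)))
      l <- c(l, shell$l); atom <- c(atom, i - 1L)
      exps <- c(exps, list(a)); coefs <- c(coefs, list(c0 / nrm))
    }
  }
  nbf <- sum(ifelse(l == 0, 1L, 3L))
  list(l = l, atom = atom, exps = exps, coefs = coefs, nbf = nbf)
}
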