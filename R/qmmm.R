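# Electrostatically-embedded QM/MM molecular dynamics. The MM region enters
# the QM Hamiltonian as point charges; QM forces come from the analytic
# gradient module (classical CASCI or emulated VQE engines, hot-swappable
# mid-trajectory); MM-MM electrostatics and all Lennard-Jones interactions
# are classical. Langevin dynamics uses the BAOAB splitting.

#' MM environment of point charges with Lennard-Jones sites
#'
#' @param charges data frame with columns `x`, `y`, `z` (Angstrom) and `q`
#'   (elementary charges), or `NULL` for an empty environment.
#' @param lj_sigma,lj_eps per-site Lennard-Jones parameters (Angstrom,
#'   Hartree).
#' @param masses per-site masses (amu).
#' @return An `mm_environment`.
#' @export
mm_environment <- function(charges, lj_sigma = NULL, lj_eps = NULL,
                           masses = NULL) {
  n <- if (is.null(charges)) 0L else nrow(charges)
  if (n > 0) {
    if (is.null(lj_sigma)) lj_sigma <- rep(3.2, n)
    if (is.null(lj_eps)) lj_eps <- rep(0.1 / HARTREE_KCAL, n)
    if (is.null(masses)) masses <- rep(18, n)
  }
  structure(list(charges = charges, lj_sigma = lj_sigma, lj_eps = lj_eps,
                 masses = masses, n = n), class = "mm_environment")
}

#' @export
print.mm_environment <- function(x, ...) {
  cat(sprintf("MM environment: %d point charges (net %.3e e)\n", x$n,
              if (x$n) sum(x$charges$q) else 0))
  invisible(x)
}

#' Embed MM point charges in the molecular Hamiltonian
#'
#' Rebuilds the molecular integrals with the MM electrostatic potential in
#' the one-electron Hamiltonian and the QM-nuclei/MM-charge Coulomb energy in
#' the nuclear term.
#'
#' @param geom QM [geometry()].
#' @param mm an [mm_environment()].
#' @param basis,charge passed to [mol_integrals()].
#' @return A [mol_integrals()] object with the embedding included.
#' @export
embed_point_charges <- function(geom, mm, basis = "sto-3g", charge = 0) {
  pc <- if (mm$n > 0) mm$charges else NULL
  if (!is.null(pc)) {
    d2min <- min(vapply(seq_len(nrow(pc)), function(i)
      min(rowSums((geom$coords - matrix(as.numeric(pc[i, c("x", "y", "z")]),
                                        nrow(geom$coords), 3, byrow = TRUE))^2)), 0))
    if (d2min < 0.25) stop("MM site within 0.5 Angstrom of a QM nucleus")
  }
  mol_integrals(geom, basis, charge, point_charges = pc)
}

# ---- classical force-field pieces -----------------------------------------

# Lennard-Jones between two site sets (Lorentz-Berthelot combination);
# positions in Bohr, sigma in Angstrom, eps in Hartree
.lj_pair <- function(xi, xj, sig, eps) {
  d <- xi - xj
  r2 <- sum(d^2)
  s2 <- (sig / BOHR_ANGSTROM)^2 / r2
  s6 <- s2^3
  e <- 4 * eps * (s6^2 - s6)
  # dE/dr vector: 4 eps (-12 s12 + 6 s6)/r2 * d
  g <- 4 * eps * (-12 * s6^2 + 6 * s6) / r2 * d
  list(e = e, g = g)
}

# LJ + MM-MM Coulomb energy and gradients for the combined system
.classical_terms <- function(xqm, xmm, mm, qm_lj) {
  nq <- nrow(xqm); nm <- if (is.null(xmm)) 0 else nrow(xmm)
  e <- 0
  gq <- matrix(0, nq, 3)
  gm <- if (nm) matrix(0, nm, 3) else NULL
  if (nm == 0) return(list(e = 0, gq = gq, gm = gm))
  q <- mm$charges$q
  for (i in seq_len(nm)) {
    # QM-MM Lennard-Jones
    for (a in seq_len(nq)) {
      sig <- 0.5 * (mm$lj_sigma[i] + qm_lj$sigma[a])
      eps <- sqrt(mm$lj_eps[i] * qm_lj$eps[a])
      if (eps <= 0) next
      p <- .lj_pair(xmm[i, ], xqm[a, ], sig, eps)
      e <- e + p$e
      gm[i, ] <- gm[i, ] + p$g
      gq[a, ] <- gq[a, ] - p$g
    }
    # MM-MM Lennard-Jones and Coulomb
    if (i < nm) for (j in (i + 1):nm) {
      sig <- 0.5 * (mm$lj_sigma[i] + mm$lj_sigma[j])
      eps <- sqrt(mm$lj_eps[i] * mm$lj_eps[j])
      p <- .lj_pair(xmm[i, ], xmm[j, ], sig, eps)
      d <- xmm[i, ] - xmm[j, ]
      r <- sqrt(sum(d^2))
      ec <- q[i] * q[j] / r
      gc <- -q[i] * q[j] * d / r^3
      e <- e + p$e + ec
      gm[i, ] <- gm[i, ] + p$g + gc
      gm[j, ] <- gm[j, ] - p$g - gc
    }
  }
  list(e = e, gq = gq, gm = gm)
}

# ---- QM engines ------------------------------------------------------------

#' Construct a QM engine for QM/MM dynamics
#'
#' Engines share one contract: given the QM geometry and the MM environment
#' they return the QM(+embedding) energy and analytic forces on QM atoms and
#' MM sites. `"casci"` is the classical reference; `"vqe-exact"` runs the
#' Ry-ansatz VQE with exact expectations (trajectory-identical to CASCI);
#' `"vqe-sampled"` adds shot noise through a [measurement_plan()].
#'
#' @param method `"casci"`, `"vqe-exact"` or `"vqe-sampled"`.
#' @param basis,charge electronic-structure settings.
#' @param active active space `c(n_elec, n_orb)` or `NULL` for full space.
#' @param plan [measurement_plan()] for `"vqe-sampled"`.
#' @param ... passed to [vqe()].
#' @return A `qm_engine`.
#' @export
qm_engine <- function(method = c("casci", "vqe-exact", "vqe-sampled"),
                      basis = "sto-3g", charge = 0, active = NULL,
                      plan = NULL, ...) {
  method <- match.arg(method)
  if (method == "vqe-sampled" && is.null(plan)) plan <- measurement_plan()
  extra <- list(...)
  structure(list(method = method, basis = basis, charge = charge,
                 active = active, plan = plan, extra = extra),
            class = "qm_engine")
}

# evaluate a QM engine: energy (Hartree) + forces (Hartree/Bohr)
qm_engine_eval <- function(engine, geom, mm, seed_offset = 0) {
  ints <- embed_point_charges(geom, mm, engine$basis, engine$charge)
  spec <- if (is.null(engine$active)) NULL else
    active_space(ints, engine$active[1], engine$active[2])
  ah <- fold_active_space(ints, spec)
  if (engine$method == "casci") {
    cs <- casci(ah)
    energy <- cs$energy
    rd <- list(rdm1 = cs$rdm1, rdm2 = cs$rdm2)
  } else {
    fit <- do.call(vqe, c(list(qh = parity_transform(ah)), engine$extra))
    if (engine$method == "vqe-exact") {
      energy <- fit$energy
      rd <- measure_rdms(fit)
    } else {
      plan <- engine$plan
      plan$seed <- plan$seed + seed_offset
      est <- energy_expectation(fit$qh, fit$statevector, plan)
      energy <- est$value
      plan$seed <- plan$seed + 104729  # decorrelate RDM shots from energy shots
      rd <- measure_rdms(fit, plan)
    }
  }
  fd <- assemble_forces(force_inputs(ints, spec, rd$rdm1, rd$rdm2))
  list(energy = energy, f_qm = fd$total, f_mm = fd$mm_forces)
}

# ---- Langevin integrator ---------------------------------------------------

#' Langevin integrator configuration
#'
#' @param timestep_fs time step (fs).
#' @param temperature_K thermostat temperature (K); 0 disables the noise.
#' @param friction_ps friction constant gamma (1/ps); 0 gives velocity
#'   Verlet.
#' @param seed RNG seed for the thermostat.
#' @return An `integrator_config`.
#' @export
integrator_config <- function(timestep_fs = 0.5, temperature_K = 300,
                              friction_ps = 1, seed = 0) {
  stopifnot(timestep_fs > 0, friction_ps >= 0)
  structure(list(dt = timestep_fs * FS_AU, temperature = temperature_K,
                 gamma = friction_ps / (1000 * FS_AU), seed = seed),
            class = "integrator_config")
}

#' One BAOAB Langevin step
#'
#' B (half kick) - A (half drift) - O (Ornstein-Uhlenbeck) - A (half drift) -
#' force refresh - B (half kick). With zero friction and temperature the
#' scheme reduces to velocity Verlet.
#'
#' @param state list with `x` (positions, Bohr), `v` (velocities, a.u.),
#'   `f` (forces, Hartree/Bohr), `m` (masses, electron masses).
#' @param force_fn function(x) returning forces (same shape as `x`) and,
#'   optionally via attribute `"energy"`, the potential energy.
#' @param config an [integrator_config()].
#' @return updated state (with the new forces cached in `$f`).
#' @export
langevin_step <- function(state, force_fn, config) {
  dt <- config$dt
  m <- state$m
  v <- state$v + 0.5 * dt * state$f / m
  x <- state$x + 0.5 * dt * v
  if (config$gamma > 0 && config$temperature > 0) {
    c1 <- exp(-config$gamma * dt)
    sig <- sqrt((1 - c1^2) * KB_HARTREE * config$temperature / m)
    v <- c1 * v + sig * matrix(rnorm(length(v)), nrow(v), 3)
  } else if (config$gamma > 0) {
    v <- exp(-config$gamma * dt) * v
  }
  x <- x + 0.5 * dt * v
  f <- force_fn(x)
  v <- v + 0.5 * dt * f / m
  list(x = x, v = v, f = f, m = m,
       epot = attr(f, "energy"), eqm = attr(f, "eqm"))
}

# ---- hybrid trajectory driver ---------------------------------------------

#' Run a QM/MM trajectory with hot-swappable QM engines
#'
#' Integrates Langevin dynamics for the QM region plus MM bath, evaluating
#' QM energy and forces with the engine named by `schedule` at each step
#' (e.g. classical CASCI for some stretches, emulated VQE for others) with
#' identical state hand-off at every switch.
#'
#' @param system list with `geom` (QM [geometry()]), `mm`
#'   ([mm_environment()]), `engines` (named list of [qm_engine()]s), and
#'   optionally `qm_lj` (list `sigma`, `eps` per QM atom).
#' @param schedule character vector of engine names, one per step (recycled
#'   if length 1).
#' @param steps number of steps.
#' @param config an [integrator_config()].
#' @param v0 initial velocities (a.u.), default zero.
#' @param freeze_mm logical: hold MM sites fixed.
#' @return A `trajectory_record`: data frame `record` (time fs, energies in
#'   kcal/mol, QM energy in Hartree, engine tag) plus the coordinate history
#'   (`coords`, Angstrom) and final `state`.
#' @export
run_hybrid_trajectory <- function(system, schedule, steps,
                                  config = integrator_config(), v0 = NULL,
                                  freeze_mm = FALSE) {
  if (steps == 0)
    return(structure(list(record = data.frame(), coords = NULL, state = NULL),
                     class = "trajectory_record"))
  schedule <- rep(schedule, length.out = steps)
  missing_eng <- setdiff(unique(schedule), names(system$engines))
  if (length(missing_eng))
    stop("schedule names engines not registered: ",
         paste(missing_eng, collapse = ", "))
  geom <- system$geom
  mm <- system$mm
  nq <- nrow(geom$coords)
  nm <- mm$n
  qm_lj <- system$qm_lj
  if (is.null(qm_lj)) qm_lj <- list(sigma = rep(2.5, nq),
                                    eps = rep(0.03 / HARTREE_KCAL, nq))
  xq <- coords_bohr(geom)
  xm <- if (nm) as.matrix(mm$charges[, c("x", "y", "z")]) / BOHR_ANGSTROM else NULL
  x <- rbind(xq, xm)
  m <- c(element_mass(geom$symbols), if (nm) mm$masses) * AMU_ME
  m <- matrix(m, length(m), 3)
  set.seed(config$seed)
  v <- if (is.null(v0)) matrix(0, nrow(x), 3) else v0
  step_now <- 1L
  make_force <- function(tag) function(xall) {
    xq <- xall[seq_len(nq), , drop = FALSE]
    xm <- if (nm) xall[nq + seq_len(nm), , drop = FALSE] else NULL
    g <- geometry(geom$symbols, xq * BOHR_ANGSTROM)
    mm_now <- mm
    if (nm) mm_now$charges[, c("x", "y", "z")] <- xm * BOHR_ANGSTROM
    qe <- qm_engine_eval(system$engines[[tag]], g, mm_now,
                         seed_offset = step_now)
    cl <- .classical_terms(xq, xm, mm_now, qm_lj)
    f <- rbind(qe$f_qm - cl$gq,
               if (nm) (if (is.null(qe$f_mm)) 0 else qe$f_mm) - cl$gm)
    if (freeze_mm && nm) f[nq + seq_len(nm), ] <- 0
    attr(f, "energy") <- qe$energy + cl$e
    attr(f, "eqm") <- qe$energy
    f
  }
  state <- list(x = x, v = v, m = m)
  state$f <- make_force(schedule[1])(x)
  rec <- vector("list", steps)
  coords <- array(NA_real_, c(steps, nrow(x), 3))
  for (s in seq_len(steps)) {
    step_now <- s
    state <- langevin_step(state, make_force(schedule[s]), config)
    if (freeze_mm && nm) state$v[nq + seq_len(nm), ] <- 0
    ekin <- 0.5 * sum(state$m * state$v^2)
    epot <- state$epot
    rec[[s]] <- data.frame(
      step = s, time_fs = s * config$dt / FS_AU,
      epot_kcal = hartree_to_kcal(epot),
      ekin_kcal = hartree_to_kcal(ekin),
      etot_kcal = hartree_to_kcal(epot + ekin),
      eqm_hartree = state$eqm, engine = schedule[s],
      stringsAsFactors = FALSE)
    coords[s, , ] <- state$x * BOHR_ANGSTROM
  }
  structure(list(record = do.call(rbind, rec), coords = coords, state = state,
                 n_qm = nq), class = "trajectory_record")
}

#' @export
print.trajectory_record <- function(x, ...) {
  n <- nrow(x$record)
  cat(sprintf("QM/MM trajectory: %d steps\n", n))
  if (n) {
    cat(sprintf("  total energy: %.4f +/- %.4f kcal/mol\n",
                mean(x$record$etot_kcal), sd(x$record$etot_kcal)))
    cat(sprintf("  engines: %s\n",
                paste(unique(x$record$engine), collapse = ", ")))
  }
  invisible(x)
}

# ---- geometry monitoring ---------------------------------------------------

.angle_deg <- function(a, b, c) {
  u <- a - b; w <- c - b
  acos(sum(u * w) / sqrt(sum(u^2) * sum(w^2))) * 180 / pi
}

#' Monitor bonds and angles along a trajectory
#'
#' @param traj a `trajectory_record`.
#' @param bonds list of atom-index pairs (1-based into the combined
#'   QM-then-MM ordering).
#' @param angles list of atom-index triples.
#' @return named list per observable with `series`, `mean`, `sd` (Angstrom /
#'   degrees).
#' @export
monitor_geometry <- function(traj, bonds = list(), angles = list()) {
  nat <- dim(traj$coords)[2]
  chk <- function(i) if (any(i < 1 | i > nat)) stop("invalid atom index")
  out <- list()
  for (b in bonds) {
    chk(b)
    s <- apply(traj$coords, 1, function(xy)
      sqrt(sum((xy[b[1], ] - xy[b[2], ])^2)))
    out[[paste0("bond_", b[1], "_", b[2])]] <-
      list(series = s, mean = mean(s), sd = sd(s))
  }
  for (a in angles) {
    chk(a)
    s <- apply(traj$coords, 1, function(xy)
      .angle_deg(xy[a[1], ], xy[a[2], ], xy[a[3], ]))
    out[[paste0("angle_", paste(a, collapse = "_"))]] <-
      list(series = s, mean = mean(s), sd = sd(s))
  }
  out
}
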