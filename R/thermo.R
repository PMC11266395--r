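# Gibbs free-energy reaction profiles: aggregate repeated sampled-VQE runs,
# assemble barrier and reaction free energies with Gaussian uncertainty
# propagation, and classify physiological accessibility.

#' Per-species Gibbs energy
#'
#' @param label species name.
#' @param energy single Gibbs energy (Hartree), or `NULL` when `repeats`
#'   given.
#' @param repeats energies from repeated sampled-VQE runs (Hartree).
#' @param gibbs_correction additive thermal correction (Hartree), if the
#'   energy is electronic-only.
#' @param formula optional chemical formula (e.g. `"C15H14O5"`) used for
#'   stoichiometry mass-balance checks.
#' @return A `species_energy`.
#' @export
species_energy <- function(label, energy = NULL, repeats = NULL,
                           gibbs_correction = 0, formula = NULL) {
  if (is.null(energy) && is.null(repeats))
    stop("species ", label, ": provide energy or repeats")
  structure(list(label = label, energy = energy, repeats = repeats,
                 gibbs_correction = gibbs_correction, formula = formula),
            class = "species_energy")
}

#' Aggregate repeated experiment energies
#'
#' Sample mean and standard deviation (denominator n-1), as reported for
#' repeated independent hardware runs.
#'
#' @param repeats numeric vector of energies.
#' @return list with `mean` and `sd` (`NA` for a single value).
#' @export
aggregate_repeats <- function(repeats) {
  if (length(repeats) == 0) stop("no repeats to aggregate")
  list(mean = mean(repeats),
       sd = if (length(repeats) >= 2) sd(repeats) else NA_real_)
}

# mean/sd Gibbs energy of one species (Hartree)
.species_g <- function(sp) {
  if (!is.null(sp$repeats)) {
    ag <- aggregate_repeats(sp$repeats)
    list(g = ag$mean + sp$gibbs_correction, sd = ifelse(is.na(ag$sd), 0, ag$sd))
  } else list(g = sp$energy + sp$gibbs_correction, sd = 0)
}

.parse_formula <- function(f) {
  m <- gregexpr("([A-Z][a-z]?)(\\d*)", f)[[1]]
  parts <- regmatches(f, gregexpr("([A-Z][a-z]?)(\\d*)", f))[[1]]
  el <- sub("\\d+$", "", parts)
  cnt <- as.integer(sub("^[A-Za-z]+", "", parts))
  cnt[is.na(cnt)] <- 1L
  tapply(cnt, el, sum)
}

.sum_formulas <- function(species) {
  tot <- list()
  for (sp in species) {
    if (is.null(sp$formula)) return(NULL)
    f <- .parse_formula(sp$formula)
    for (el in names(f)) tot[[el]] <- (tot[[el]] %||% 0) + f[[el]]
  }
  tot
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a Gibbs free-energy reaction profile
#'
#' Computes the activation barrier `dG_barrier = G(TS) - sum G(reactants)`
#' and the reaction free energy `dG_reaction = sum G(products) - sum
#' G(reactants)` in kcal/mol (conversion 627.5095), with uncertainties
#' propagated as the root-sum-square of independent per-species standard
#' deviations. If all species carry formulas, reactant/product atom counts
#' are checked for mass balance.
#'
#' @param species list of [species_energy()] objects.
#' @param reactants,transition_state,products species labels (vectors for
#'   stoichiometric sums).
#' @return A `reaction_profile` with `dG_barrier`, `dG_reaction` (kcal/mol)
#'   and their `sd`s.
#' @export
assemble_profile <- function(species, reactants, transition_state, products) {
  byname <- stats::setNames(species, vapply(species, `[[`, "", "label"))
  need <- c(reactants, transition_state, products)
  missing <- setdiff(need, names(byname))
  if (length(missing)) stop("species missing: ", paste(missing, collapse = ", "))
  fr <- .sum_formulas(byname[reactants])
  fp <- .sum_formulas(byname[products])
  if (!is.null(fr) && !is.null(fp)) {
    all_el <- union(names(fr), names(fp))
    for (el in all_el)
      if ((fr[[el]] %||% 0) != (fp[[el]] %||% 0))
        stop("stoichiometry not mass-balanced for element ", el)
  }
  gsum <- function(labels) {
    gs <- lapply(byname[labels], .species_g)
    list(g = sum(vapply(gs, `[[`, 0, "g")),
         var = sum(vapply(gs, `[[`, 0, "sd")^2))
  }
  R <- gsum(reactants); TS <- gsum(transition_state); P <- gsum(products)
  structure(list(
    reactants = reactants, transition_state = transition_state,
    products = products,
    dG_barrier = hartree_to_kcal(TS$g - R$g),
    dG_barrier_sd = hartree_to_kcal(sqrt(TS$var + R$var)),
    dG_reaction = hartree_to_kcal(P$g - R$g),
    dG_reaction_sd = hartree_to_kcal(sqrt(P$var + R$var))
  ), class = "reaction_profile")
}

#' @export
print.reaction_profile <- function(x, ...) {
  cat(sprintf("Reaction profile: %s -> %s -> %s\n",
              paste(x$reactants, collapse = " + "),
              paste(x$transition_state, collapse = " + "),
              paste(x$products, collapse = " + ")))
  fmt <- function(v, s) if (s > 0) sprintf("%.1f +/- %.1f", v, s) else sprintf("%.1f", v)
  cat(sprintf("  dG_barrier  = %s kcal/mol\n", fmt(x$dG_barrier, x$dG_barrier_sd)))
  cat(sprintf("  dG_reaction = %s kcal/mol\n", fmt(x$dG_reaction, x$dG_reaction_sd)))
  invisible(x)
}

#' Classify physiological accessibility and spontaneity
#'
#' A barrier below 20 kcal/mol (strict) is flagged as physiologically
#' accessible; a negative reaction free energy as thermodynamically
#' favorable; a negative barrier as non-physical (with a warning).
#'
#' @param profile a [assemble_profile()] result.
#' @return list with logical `accessible`, `favorable`, `nonphysical_barrier`.
#' @export
classify_spontaneity <- function(profile) {
  nonphys <- profile$dG_barrier < 0
  if (nonphys)
    warning("negative reaction barrier is non-physical (sampling noise?)")
  list(accessible = profile$dG_barrier < 20 && !nonphys,
       favorable = profile$dG_reaction < 0,
       nonphysical_barrier = nonphys)
}

#' Packaged prodrug-activation species energies
#'
#' Published per-species Gibbs free energies (Hartree) for the
#' beta-lapachone-derived prodrug C-C bond-cleavage reaction
#' `4 -> TS -> 5 + 6 + H2O`, computed with HF, CASCI(2e,2o) and four repeated
#' 2-qubit VQE hardware runs, with and without continuum solvent.
#'
#' @param method `"HF"`, `"CASCI"` or `"VQE"`.
#' @param solvent `"with"` or `"without"`.
#' @return list of [species_energy()] objects.
#' @examples
#' prof <- assemble_profile(prodrug_species("HF", "with"),
#'                          reactants = "4", transition_state = "TS",
#'                          products = c("5", "6", "H2O"))
#' round(prof$dG_barrier, 1)  # 13.1 kcal/mol
#' @export
prodrug_species <- function(method = c("HF", "CASCI", "VQE"),
                            solvent = c("with", "without")) {
  method <- match.arg(method)
  solvent <- match.arg(solvent)
  path <- system.file("extdata", "prodrug_species_gibbs.csv",
                      package = "vqemol", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$method == method & df$solvent == solvent,
           c("label", "energy", "repeat_id")]
  out <- list()
  for (lab in unique(df$label)) {
    rows <- df[df$label == lab, , drop = FALSE]
    out[[length(out) + 1L]] <- if (nrow(rows) > 1)
      species_energy(lab, repeats = rows$energy)
    else species_energy(lab, energy = rows$energy)
  }
  out
}

#' Read a species-energy table from CSV
#'
#' Long format with columns `label`, `energy` (Hartree), optional `repeat_id`
#' (rows with the same label and distinct repeat ids are collected into
#' repeats), optional `gibbs_correction`, optional `formula`.
#'
#' @param path CSV file.
#' @return list of [species_energy()] objects.
#' @export
read_species_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (lab in unique(df$label)) {
    rows <- df[df$label == lab, , drop = FALSE]
    gc <- if ("gibbs_correction" %in% names(rows)) rows$gibbs_correction[1] else 0
    fo <- if ("formula" %in% names(rows)) rows$formula[1] else NULL
    if (!is.null(fo) && (is.na(fo) || fo == "")) fo <- NULL
    if (nrow(rows) > 1)
      out[[lab]] <- species_energy(lab, repeats = rows$energy,
                                   gibbs_correction = gc, formula = fo)
    else
      out[[lab]] <- species_energy(lab, energy = rows$energy,
                                   gibbs_correction = gc, formula = fo)
  }
  unname(out)
}
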