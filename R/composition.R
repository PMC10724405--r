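#' Species specification table for crystallin-like hard spheres
#'
#' Builds a validated table of per-species physical parameters.  Each row
#' describes one particle species by its hydrodynamic (DLS) diameter, the
#' mass of a single particle, its relative mass abundance in the mixture,
#' and its molecular weight.
#'
#' @param name character vector of species labels.
#' @param diameter_nm positive numeric, particle diameter in nanometres.
#' @param mass_g positive numeric, single-particle mass in grams.
#' @param mass_ratio non-negative numeric, relative mass abundance
#'   (arbitrary units; only ratios matter).
#' @param mw_kda positive numeric, molecular weight in kilodaltons.
#' @return a `data.frame` of class `species_spec` with one row per species.
#' @examples
#' species_spec(c("alpha", "gamma"), c(18.6, 3.56),
#'              c(1.13e-18, 3.49e-20), c(35, 21), c(680, 21))
#' @export
species_spec <- function(name, diameter_nm, mass_g,
                         mass_ratio = rep(1, length(name)),
                         mw_kda = rep(1, length(name))) {
  n <- length(name)
  stopifnot(n >= 1)
  if (length(diameter_nm) != n || length(mass_g) != n ||
      length(mass_ratio) != n || length(mw_kda) != n) {
    stop("all species columns must have the same length")
  }
  if (any(!is.finite(diameter_nm)) || any(diameter_nm <= 0)) {
    stop("diameter_nm must be positive and finite")
  }
  if (any(!is.finite(mass_g)) || any(mass_g <= 0)) {
    stop("mass_g must be positive and finite")
  }
  if (any(!is.finite(mass_ratio)) || any(mass_ratio < 0)) {
    stop("mass_ratio must be non-negative")
  }
  if (any(!is.finite(mw_kda)) || any(mw_kda <= 0)) {
    stop("mw_kda must be positive")
  }
  out <- data.frame(name = as.character(name), diameter_nm = diameter_nm,
                    mass_g = mass_g, mass_ratio = mass_ratio,
                    mw_kda = mw_kda, stringsAsFactors = FALSE)
  class(out) <- c("species_spec", "data.frame")
  out
}

#' Crystallin species table (bovine lens, DLS-derived)
#'
#' The packaged preset of the three crystallin subtypes used throughout
#' the simulations: alpha (18.6 nm, 1.13e-18 g, MW 680 kDa), beta
#' (11.7 nm, 2.99e-19 g, 180 kDa, representative of the beta-H oligomer)
#' and gamma (3.56 nm, 3.49e-20 g, 21 kDa).  Mass ratios are the native
#' lens-average 35:37:21.
#'
#' @return a `species_spec` table with rows alpha, beta, gamma.
#' @export
crystallin_species <- function() {
  species_spec(name = c("alpha", "beta", "gamma"),
               diameter_nm = c(18.6, 11.7, 3.56),
               mass_g = c(1.13e-18, 2.99e-19, 3.49e-20),
               mass_ratio = c(35, 37, 21),
               mw_kda = c(680, 180, 21))
}

#' Convert a species table to reduced (dimensionless) simulation units
#'
#' The natural unit of length is the diameter sigma of the largest
#' species and the natural unit of mass is its particle mass m, so the
#' reference species has reduced diameter and mass exactly 1 and every
#' other species a value in (0, 1].  Mole fractions may be supplied
#' directly or computed from the mass ratios and molecular weights via
#' [mole_fractions_from_mass()].
#'
#' @param specs a `species_spec` table.
#' @param mole_fraction optional per-species mole fractions summing to 1.
#'   When `NULL` they are computed from `mass_ratio` / `mw_kda`.
#' @return an object of class `species_set`: a list with the spec table,
#'   `mole_fraction`, the reference scales `sigma_nm` / `m_ref_g`, and the
#'   full-precision `reduced_diameter` / `reduced_mass` vectors.
#' @examples
#' to_reduced_units(crystallin_species())
#' @export
to_reduced_units <- function(specs, mole_fraction = NULL) {
  if (!inherits(specs, "species_spec")) {
    specs <- do.call(species_spec, as.list(specs))
  }
  if (nrow(specs) < 1) stop("need at least one species")
  if (is.null(mole_fraction)) {
    mole_fraction <- mole_fractions_from_mass(specs$mass_ratio, specs$mw_kda)
  }
  if (length(mole_fraction) != nrow(specs)) {
    stop("mole_fraction length must match number of species")
  }
  if (any(mole_fraction < 0)) stop("mole fractions must be non-negative")
  if (abs(sum(mole_fraction) - 1) > 1e-12) {
    stop("mole fractions must sum to 1 (within 1e-12)")
  }
  ref <- which.max(specs$diameter_nm)
  out <- list(species = specs,
              mole_fraction = mole_fraction,
              sigma_nm = specs$diameter_nm[ref],
              m_ref_g = specs$mass_g[ref],
              reduced_diameter = specs$diameter_nm / specs$diameter_nm[ref],
              reduced_mass = specs$mass_g / specs$mass_g[ref])
  class(out) <- "species_set"
  out
}

#' @export
print.species_set <- function(x, ...) {
  cat("Reduced-unit species set (sigma =", format(x$sigma_nm), "nm, m =",
      format(x$m_ref_g), "g)\n")
  tab <- data.frame(name = x$species$name,
                    d_sigma = round(x$reduced_diameter, 2),
                    m_ref = round(x$reduced_mass, 2),
                    mole_fraction = round(x$mole_fraction, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Mole fractions from mass ratios and molecular weights
#'
#' Converts relative mass abundances into mole fractions:
#' `x_i = (ratio_i / MW_i) / sum_j (ratio_j / MW_j)`.  The result is
#' invariant to rescaling all mass ratios by a common factor.
#'
#' @param mass_ratios positive relative mass abundances.
#' @param mw_kda positive molecular weights (any common unit).
#' @return numeric mole-fraction vector summing to 1.
#' @examples
#' mole_fractions_from_mass(c(35, 37, 21), c(680, 180, 21))
#' @export
mole_fractions_from_mass <- function(mass_ratios, mw_kda) {
  if (length(mass_ratios) != length(mw_kda)) {
    stop("mass_ratios and mw_kda must have equal length")
  }
  if (any(mass_ratios <= 0) || any(mw_kda <= 0)) {
    stop("mass ratios and molecular weights must be positive")
  }
  moles <- mass_ratios / mw_kda
  moles / sum(moles)
}

#' Lens mixture composition preset
#'
#' The three-species reduced-unit composition used in the crowding
#' simulations.  Two mole-fraction routes are exposed: `"lens"` uses the
#' published lens-average mole fractions 0.05:0.20:0.75 (alpha:beta:gamma)
#' verbatim, while `"mass_ratio"` recomputes fractions from the printed
#' native mass ratios 35:37:21 and molecular weights 680/180/21 kDa
#' (which gives approximately 0.041:0.164:0.795).  The two differ because
#' the published mole fractions derive from lens-averaged composition
#' data that are not identical to the rounded 35:37:21 ratio; both paths
#' are kept so either world can be simulated.
#'
#' @param source `"lens"` (default) or `"mass_ratio"`.
#' @return a `species_set`.
#' @export
lens_composition <- function(source = c("lens", "mass_ratio")) {
  source <- match.arg(source)
  specs <- crystallin_species()
  if (source == "lens") {
    to_reduced_units(specs, mole_fraction = c(0.05, 0.20, 0.75))
  } else {
    to_reduced_units(specs)
  }
}

#' Packing fraction of a sphere mixture in a cubic box
#'
#' `phi = sum_i n_i (pi/6) d_i^3 / L^3` for counts `n_i`, reduced
#' diameters `d_i` and box edge `L` (all lengths in the same unit).
#'
#' @param counts non-negative integer per-species particle counts.
#' @param reduced_diameters per-species diameters.
#' @param box_edge box edge length, must be positive.
#' @return the dimensionless packing (volume) fraction.
#' @examples
#' packing_fraction(1, 1, 1)  # pi/6
#' @export
packing_fraction <- function(counts, reduced_diameters, box_edge) {
  if (length(box_edge) != 1 || !is.finite(box_edge) || box_edge <= 0) {
    stop("box_edge must be a single positive number")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(counts) != length(reduced_diameters)) {
    stop("counts and reduced_diameters must have equal length")
  }
  sum(counts * (pi / 6) * reduced_diameters^3) / box_edge^3
}

#' Box edge that realizes a target packing fraction
#'
#' @param counts per-species particle counts.
#' @param reduced_diameters per-species diameters.
#' @param phi target packing fraction in (0, 1).
#' @return box edge length in the diameter unit.
#' @export
box_edge_for_phi <- function(counts, reduced_diameters, phi) {
  stopifnot(phi > 0, phi < 1)
  (sum(counts * (pi / 6) * reduced_diameters^3) / phi)^(1 / 3)
}

#' Integer particle counts from mole fractions (largest-remainder rounding)
#'
#' Rounds `fraction_i * n_total` down and then distributes the remaining
#' particles to the species with the largest fractional remainders, so the
#' counts always sum to `n_total` exactly.  Ties are broken by species
#' order.
#'
#' @param set a `species_set` (or a bare numeric mole-fraction vector).
#' @param n_total total particle count, at least 1.
#' @return integer vector of per-species counts summing to `n_total`.
#' @examples
#' realize_counts(c(0.05, 0.20, 0.75), 1000)
#' @export
realize_counts <- function(set, n_total) {
  fractions <- if (inherits(set, "species_set")) set$mole_fraction else set
  if (n_total < 1) stop("n_total must be at least 1")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  ideal <- fractions * n_total
  counts <- floor(ideal)
  short <- n_total - sum(counts)
  if (short > 0) {
    rem <- ideal - counts
    give <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[give] <- counts[give] + 1
  }
  as.integer(counts)
}

#' Mass-preserving exclusion of a species from a composition
#'
#' Removes one species from a mixture while retaining the same overall
#' mass: the remaining species keep their relative proportions (mole
#' fractions renormalized over the survivors) and the total protein mass
#' is restored by scaling the particle number -- at a fixed packing
#' fraction the simulation box simply adjusts.  For a fixed-n simulation
#' only the renormalized composition matters; the implied particle-count
#' scale factor is returned as an attribute.
#'
#' @param set a `species_set`.
#' @param exclude name of the species to remove.
#' @return a `species_set` without the excluded species; attribute
#'   `n_scale` is the particle-count factor that restores the original
#'   total mass.
#' @export
exclude_species <- function(set, exclude) {
  stopifnot(inherits(set, "species_set"))
  idx <- match(exclude, set$species$name)
  if (is.na(idx)) stop("unknown species: ", exclude)
  if (nrow(set$species) < 2) stop("cannot exclude the only species")
  keep <- setdiff(seq_len(nrow(set$species)), idx)
  x_new <- set$mole_fraction[keep] / sum(set$mole_fraction[keep])
  out <- to_reduced_units(set$species[keep, , drop = FALSE],
                          mole_fraction = x_new)
  mass_full <- sum(set$mole_fraction * set$reduced_mass)
  mass_kept <- sum(x_new * set$reduced_mass[keep])
  attr(out, "n_scale") <- mass_full / mass_kept
  out
}
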