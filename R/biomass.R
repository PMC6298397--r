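#' Biomass composition
#'
#' Macromolecular composition of the cell used to build the biomass
#' objective: mass fractions (g/gDW) over protein, DNA, RNA, lipid, glucan,
#' chitin and small molecules, plus monomer mole-fraction profiles and the
#' growth-associated ATP maintenance. The shipped default
#' ([default_biomass_composition()]) is a documented placeholder profile
#' for an EPS-producing basidiomycete and is meant to be overridden with
#' measured data.
#'
#' @param mass_fractions Named numeric, g/gDW over
#'   `protein, dna, rna, lipid, glucan, chitin, small_molecules`;
#'   must be non-negative and sum to 1 (tolerance 1e-6).
#' @param amino_acid_mole_fractions Named numeric over the 20 amino acids,
#'   summing to 1. Default: uniform.
#' @param nucleotide_mole_fractions Named numeric over `a, c, g, u`,
#'   summing to 1. Default: uniform.
#' @param rna_dna_ratio RNA:DNA mass ratio (metadata; default 6).
#' @param gam_atp Growth-associated maintenance, mmol ATP/gDW (default 40).
#' @return A list of class `biomass_composition`.
#' @export
biomass_composition <- function(mass_fractions,
                                amino_acid_mole_fractions = NULL,
                                nucleotide_mole_fractions = NULL,
                                rna_dna_ratio = 6, gam_atp = 40) {
  comp_names <- c("protein", "dna", "rna", "lipid", "glucan", "chitin", "small_molecules")
  stopifnot(is.numeric(mass_fractions), !is.null(names(mass_fractions)))
  unknown <- setdiff(names(mass_fractions), comp_names)
  if (length(unknown))
    stop(sprintf("unknown biomass component(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (any(mass_fractions < 0)) stop("mass fractions must be >= 0", call. = FALSE)
  if (abs(sum(mass_fractions) - 1) > 1e-6)
    stop(sprintf("mass fractions sum to %.8f, not 1", sum(mass_fractions)), call. = FALSE)
  if (is.null(amino_acid_mole_fractions))
    amino_acid_mole_fractions <- stats::setNames(rep(1 / 20, 20), amino_acid_ids())
  if (is.null(nucleotide_mole_fractions))
    nucleotide_mole_fractions <- stats::setNames(rep(0.25, 4), c("a", "c", "g", "u"))
  for (mf in list(amino_acid_mole_fractions, nucleotide_mole_fractions)) {
    if (abs(sum(mf) - 1) > 1e-6) stop("mole fractions must sum to 1", call. = FALSE)
    if (any(mf < 0)) stop("mole fractions must be >= 0", call. = FALSE)
  }
  stopifnot(gam_atp >= 0)
  structure(list(mass_fractions = mass_fractions,
                 amino_acid_mole_fractions = amino_acid_mole_fractions,
                 nucleotide_mole_fractions = nucleotide_mole_fractions,
                 rna_dna_ratio = rna_dna_ratio, gam_atp = gam_atp),
            class = "biomass_composition")
}

#' @rdname biomass_composition
#' @export
default_biomass_composition <- function() {
  biomass_composition(c(protein = 0.42, dna = 0.01, rna = 0.06, lipid = 0.08,
                        glucan = 0.28, chitin = 0.05, small_molecules = 0.10))
}

#' EPS monosaccharide composition
#'
#' Mole percentages of the seven monosaccharides found in fungal
#' extracellular polysaccharides. Glucose must be the largest share
#' (fucose and rhamnose are characteristically minor). The default is a
#' representative glucose-dominated profile.
#'
#' @param mole_percent Named numeric over
#'   `glucose, galactose, mannose, xylose, arabinose, fucose, rhamnose`,
#'   non-negative, summing to 100 (tolerance 1e-6).
#' @return A list of class `eps_composition`.
#' @export
eps_composition <- function(mole_percent) {
  sugars <- c("glucose", "galactose", "mannose", "xylose", "arabinose",
              "fucose", "rhamnose")
  stopifnot(is.numeric(mole_percent), !is.null(names(mole_percent)))
  unknown <- setdiff(names(mole_percent), sugars)
  if (length(unknown))
    stop(sprintf("unknown monosaccharide(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (any(mole_percent < 0)) stop("mole percentages must be >= 0", call. = FALSE)
  if (abs(sum(mole_percent) - 100) > 1e-6)
    stop(sprintf("mole percentages sum to %.6f, not 100", sum(mole_percent)),
         call. = FALSE)
  glc <- if ("glucose" %in% names(mole_percent)) mole_percent[["glucose"]] else 0
  if (glc < max(mole_percent))
    stop("glucose must be the largest monosaccharide share", call. = FALSE)
  structure(list(mole_percent = mole_percent), class = "eps_composition")
}

#' @rdname eps_composition
#' @export
default_eps_composition <- function() {
  eps_composition(c(glucose = 60, galactose = 15, mannose = 10, xylose = 6,
                    arabinose = 5, fucose = 2, rhamnose = 2))
}

#' Build the biomass objective reaction
#'
#' Converts mass fractions (g/gDW) into molar drains (mmol/gDW) through the
#' precursor registry's molar masses - `coefficient = 1000 * fraction /
#' molar_mass` - and adds the growth-associated ATP hydrolysis
#' (`gam_atp` ATP + H2O -> ADP + Pi + H) when the registry maps the energy
#' species. The resulting pseudo-reaction is a sink whose flux is the
#' specific growth rate (1/h); re-multiplying its molar coefficients by the
#' molar masses recovers 1 g/gDW exactly (mass closure).
#'
#' @param composition A [biomass_composition()].
#' @param precursor_registry `data.frame` with columns `component` (names
#'   of `mass_fractions`, plus optionally `atp`, `adp`, `pi`, `h2o`, `h`),
#'   `metabolite_id`, `molar_mass` (g/mol of the drained residue; `NA` for
#'   the energy species).
#' @param id Reaction id (default `"BIOMASS"`).
#' @param subsystem Subsystem label (default `"other"`).
#' @return A [reaction()].
#' @examples
#' reg <- data.frame(component = "glucan", metabolite_id = "glucan_c",
#'                   molar_mass = 162.14)
#' comp <- biomass_composition(c(glucan = 1), gam_atp = 0)
#' build_biomass_reaction(comp, reg)$stoichiometry  # -6.167 mmol/gDW glucan
#' @export
build_biomass_reaction <- function(composition, precursor_registry, id = "BIOMASS",
                                   subsystem = "other") {
  stopifnot(inherits(composition, "biomass_composition"),
            is.data.frame(precursor_registry),
            all(c("component", "metabolite_id", "molar_mass") %in% names(precursor_registry)))
  mf <- composition$mass_fractions
  mf <- mf[mf > 0]
  st <- numeric(0)
  for (comp in names(mf)) {
    row <- precursor_registry[precursor_registry$component == comp, , drop = FALSE]
    if (nrow(row) == 0)
      stop(sprintf("precursor registry has no entry for component '%s'", comp),
           call. = FALSE)
    if (is.na(row$molar_mass[1]) || row$molar_mass[1] <= 0)
      stop(sprintf("component '%s' needs a positive molar mass", comp), call. = FALSE)
    mid <- row$metabolite_id[1]
    st[mid] <- (if (mid %in% names(st)) st[[mid]] else 0) - 1000 * mf[[comp]] / row$molar_mass[1]
  }
  if (composition$gam_atp > 0) {
    energy <- c(atp = -1, h2o = -1, adp = 1, pi = 1, h = 1) * composition$gam_atp
    for (comp in names(energy)) {
      row <- precursor_registry[precursor_registry$component == comp, , drop = FALSE]
      if (nrow(row) == 0) {
        if (comp == "atp")
          stop("gam_atp > 0 but the registry does not map 'atp'", call. = FALSE)
        next  # h2o/h etc. optional in reduced models
      }
      mid <- row$metabolite_id[1]
      st[mid] <- (if (mid %in% names(st)) st[[mid]] else 0) + energy[[comp]]
    }
  }
  reaction(id, st, name = "biomass objective", lower_bound = 0, upper_bound = 1000,
           subsystem = subsystem)
}

#' Build the EPS target reaction from monosaccharide mole percentages
#'
#' The EPS sink drains the activated nucleotide-sugar donor of each
#' monosaccharide in the measured mole ratios, normalized to 1 mmol total
#' monosaccharide per flux unit, and releases the corresponding NDP/NMP
#' carrier. The canonical donor mapping is glucose -> UDP-glucose,
#' galactose -> UDP-galactose, mannose -> GDP-mannose, fucose ->
#' GDP-fucose, xylose -> UDP-xylose, arabinose -> UDP-arabinose,
#' rhamnose -> dTDP-rhamnose. Coefficients are homogeneous of degree one in
#' the composition: scaling all percentages by a constant changes nothing.
#'
#' @param eps An [eps_composition()].
#' @param nucleotide_sugar_registry `data.frame` with columns `sugar`,
#'   `donor_id` (nucleotide-sugar metabolite), `released_id` (the NDP/NMP
#'   set free on transfer).
#' @param id Reaction id (default `"EPS"`).
#' @param eps_metabolite Id of the polysaccharide product metabolite;
#'   `NULL` makes the reaction a pure sink.
#' @param atp_per_bond Optional polymerization energy: ATP equivalents
#'   hydrolysed per glycosidic bond (default 0; requires `atp_id`/`adp_id`).
#' @param atp_id,adp_id Metabolite ids for the polymerization energy term.
#' @param subsystem Subsystem label (default `"GB"`).
#' @return A [reaction()].
#' @export
build_eps_reaction <- function(eps, nucleotide_sugar_registry, id = "EPS",
                               eps_metabolite = "eps", atp_per_bond = 0,
                               atp_id = "atp", adp_id = "adp", subsystem = "GB") {
  stopifnot(inherits(eps, "eps_composition"), is.data.frame(nucleotide_sugar_registry),
            all(c("sugar", "donor_id", "released_id") %in% names(nucleotide_sugar_registry)))
  mp <- eps$mole_percent
  mp <- mp[mp > 0]
  frac <- mp / sum(mp)   # normalize to 1 mmol total monosaccharide
  st <- numeric(0)
  add <- function(st, mid, coef) {
    st[mid] <- (if (mid %in% names(st)) st[[mid]] else 0) + coef
    st
  }
  for (sugar in names(frac)) {
    row <- nucleotide_sugar_registry[nucleotide_sugar_registry$sugar == sugar, , drop = FALSE]
    if (nrow(row) == 0)
      stop(sprintf("nucleotide-sugar registry has no donor for '%s'", sugar),
           call. = FALSE)
    st <- add(st, row$donor_id[1], -frac[[sugar]])
    st <- add(st, row$released_id[1], frac[[sugar]])
  }
  if (atp_per_bond > 0) {
    st <- add(st, atp_id, -atp_per_bond)
    st <- add(st, adp_id, atp_per_bond)
  }
  if (!is.null(eps_metabolite)) st <- add(st, eps_metabolite, 1)
  reaction(id, st, name = "EPS target equation", lower_bound = 0,
           upper_bound = 1000, subsystem = subsystem)
}

#' Canonical nucleotide-sugar donor mapping
#'
#' @return `data.frame` mapping each EPS monosaccharide to its activated
#'   donor and the carrier released on transfer, using the package's short
#'   metabolite ids.
#' @export
nucleotide_sugar_donors <- function() {
  data.frame(
    sugar = c("glucose", "galactose", "mannose", "fucose", "xylose",
              "arabinose", "rhamnose"),
    donor_id = c("udpg", "udpgal", "gdpman", "gdpfuc", "udpxyl",
                 "udparab", "dtdprha"),
    released_id = c("udp", "udp", "gdp", "gdp", "udp", "udp", "tdp"),
    stringsAsFactors = FALSE)
}
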