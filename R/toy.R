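#' Specification for a seeded toy metabolic model
#'
#' The generator emits a compartment-free core carbon network - carbon
#' source exchanges feeding hexose phosphate through kinase steps, a lumped
#' glycolytic ATP module, amino-acid synthesis and a biomass sink - and,
#' optionally, the nucleotide-sugar branch of EPS biosynthesis
#' (phosphoglucomutase, UTP-glucose pyrophosphorylase, UDP-glucose
#' 4-epimerase, UDP-glucose 6-dehydrogenase, UDP-xylose/arabinose
#' epimerization, the mannose-6-P -> GDP-mannose -> GDP-fucose arm and the
#' dTDP-rhamnose arm) terminating in an EPS sink built by
#' [build_eps_reaction()]. Substrate yields are drawn from a small rational
#' set so all optima are exact fractions; the seed fully determines the
#' model.
#'
#' @param n_carbon_sources Number of carbon sources (>= 1; glucose plus
#'   `n - 1` alternatives).
#' @param include_eps_pathway Add the nucleotide-sugar branch, EPS sink and
#'   the gap-injectable side branch.
#' @param n_isozyme_pairs Number of reactions whose single gene is replaced
#'   by an isozyme pair (OR rule); capped by the eligible reactions.
#' @param n_planted_essential Number of extra planted single-gene steps on
#'   the biomass-precursor path, in addition to the three core catabolic
#'   genes that are essential by construction.
#' @param inject_gap Apply [inject_gap()] to the generated model.
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `toy_model_spec`.
#' @export
toy_model_spec <- function(n_carbon_sources = 3, include_eps_pathway = TRUE,
                           n_isozyme_pairs = 1, n_planted_essential = 2,
                           inject_gap = FALSE, seed = 0) {
  stopifnot(n_carbon_sources >= 1, n_isozyme_pairs >= 0, n_planted_essential >= 0)
  structure(list(n_carbon_sources = as.integer(n_carbon_sources),
                 include_eps_pathway = isTRUE(include_eps_pathway),
                 n_isozyme_pairs = as.integer(n_isozyme_pairs),
                 n_planted_essential = as.integer(n_planted_essential),
                 inject_gap = isTRUE(inject_gap), seed = as.integer(seed)),
            class = "toy_model_spec")
}

with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a toy metabolic model with planted ground truth
#'
#' See [toy_model_spec()] for the emitted topology. The returned truth
#' carries the planted essential-gene sets for growth (minimal and
#' fermentation media) and for EPS synthesis, the expected sole-source
#' phenotype calls, closed-form maximal growth and EPS rates derived from
#' the network's rational yield structure (and cross-checked against FBA at
#' generation time), and - for EPS-bearing models - the top overexpression
#' target re-derived through the screen itself.
#'
#' @param spec A [toy_model_spec()] (or an integer, shorthand for
#'   `toy_model_spec(seed = spec)`).
#' @return A list with elements `model` (a `metabolic_model`) and `truth`
#'   (class `toy_model_truth`: `essential_genes_growth`,
#'   `essential_genes_growth_fermentation`, `essential_genes_eps`,
#'   `expected_phenotype_calls`, `analytic_max_growth`, `analytic_max_eps`,
#'   `top_overexpression_target`, `media`, `gap_metabolite`).
#' @export
generate_toy_model <- function(spec = toy_model_spec()) {
  if (is.numeric(spec)) spec <- toy_model_spec(seed = spec)
  stopifnot(inherits(spec, "toy_model_spec"))
  with_preserved_seed(spec$seed, build_toy_model(spec))
}

build_toy_model <- function(spec) {
  mets <- list(
    metabolite("glc", "glucose", formula = "C6"),
    metabolite("nh4", "ammonium", formula = "N1"),
    metabolite("pi", "phosphate", formula = "P1"),
    metabolite("g6p", "glucose-6-phosphate", formula = "C6P1"),
    metabolite("atp", "ATP", formula = "C10P3"),
    metabolite("adp", "ADP", formula = "C10P2"),
    metabolite("pyr", "pyruvate", formula = "C3"),
    metabolite("aa", "amino-acid pool", formula = "C3N1"))
  # the phenotype appendage (an assimilable amino acid plus two
  # non-catabolizable substrates) rides along whenever the spec asks for
  # more than the bare single-source core, keeping that core at <= 10
  # reactions for exhaustive oracles
  appendage <- spec$include_eps_pathway || spec$n_carbon_sources > 1
  if (appendage) {
    mets <- c(mets, list(
      metabolite("phe", "phenylalanine", formula = "C3N1"),
      metabolite("ino", "inositol", formula = "C6"),
      metabolite("ure", "urea", formula = "C1N2")))
  }
  # seeded rational coefficients: biomass a*aa + b*g6p + c*atp
  a <- sample(1:2, 1); b <- sample(1:2, 1); c_atp <- sample(1:2, 1)
  rxns <- list(
    reaction("EX_glc", c(glc = -1), lower_bound = -10, subsystem = "ER"),
    reaction("EX_nh4", c(nh4 = -1), lower_bound = -1000, subsystem = "ER"),
    reaction("EX_pi", c(pi = -1), lower_bound = -1000, subsystem = "ER"),
    reaction("EX_pyr", c(pyr = -1), lower_bound = 0, subsystem = "ER"),
    reaction("HEX", c(glc = -1, atp = -1, g6p = 1, adp = 1),
             name = "hexokinase", gpr = "gHK", subsystem = "CM"),
    reaction("GLYC", c(g6p = -1, adp = -2, pi = -1, atp = 2, pyr = 2),
             name = "lumped glycolysis", gpr = "gPFK", subsystem = "CM"),
    reaction("AAS", c(pyr = -1, nh4 = -1, atp = -1, aa = 1, adp = 1, pi = 1),
             name = "amino-acid synthesis", gpr = "gAAS", subsystem = "AM"))
  if (appendage) {
    rxns <- c(rxns, list(
      reaction("EX_phe", c(phe = -1), lower_bound = 0, subsystem = "ER"),
      reaction("EX_ino", c(ino = -1), lower_bound = 0, subsystem = "ER"),
      reaction("EX_ure", c(ure = -1), lower_bound = 0, subsystem = "ER"),
      reaction("PHET", c(phe = -1, aa = 1),
               name = "phenylalanine assimilation", gpr = "gPHT", subsystem = "AM")))
  }
  carbon_pool <- c("gal", "man", "fru", "xyl", "ara", "mal", "suc", "lac")
  n_extra <- spec$n_carbon_sources - 1L
  if (n_extra > length(carbon_pool))
    stop(sprintf("at most %d extra carbon sources supported", length(carbon_pool)),
         call. = FALSE)
  extra_sources <- if (n_extra > 0) carbon_pool[seq_len(n_extra)] else character(0)
  atp_cost <- if (n_extra > 0) sample(0:1, n_extra, replace = TRUE) else integer(0)
  cat_ids <- character(0)
  for (i in seq_along(extra_sources)) {
    src <- extra_sources[i]
    mets <- c(mets, list(metabolite(src, src, formula = "C6")))
    rxns <- c(rxns, list(reaction(paste0("EX_", src), stats::setNames(-1, src),
                                  lower_bound = 0, subsystem = "ER")))
    st <- if (atp_cost[i] == 1) {
      stats::setNames(c(-1, -1, 1, 1), c(src, "atp", "g6p", "adp"))
    } else {
      stats::setNames(c(-1, -1, 1), c(src, "pi", "g6p"))
    }
    cid <- paste0("CAT_", toupper(src))
    cat_ids <- c(cat_ids, cid)
    rxns <- c(rxns, list(reaction(cid, st, name = paste(src, "catabolism"),
                                  gpr = paste0("gCAT_", toupper(src)), subsystem = "CM")))
  }
  # planted precursor chain g6p -> bp1 -> ... -> bpk feeding biomass
  chain_genes <- character(0)
  biomass_precursor <- "g6p"
  for (i in seq_len(spec$n_planted_essential)) {
    bp <- paste0("bp", i)
    mets <- c(mets, list(metabolite(bp, bp, formula = "C6P1")))
    g <- paste0("gBP", i)
    chain_genes <- c(chain_genes, g)
    rxns <- c(rxns, list(reaction(paste0("BPS", i),
                                  stats::setNames(c(-1, 1), c(biomass_precursor, bp)),
                                  name = paste("precursor step", i), gpr = g,
                                  subsystem = "CM")))
    biomass_precursor <- bp
  }
  biomass_st <- stats::setNames(c(-a, -b, -c_atp, c_atp, c_atp),
                                c("aa", biomass_precursor, "atp", "adp", "pi"))
  rxns <- c(rxns, list(reaction("BIOMASS", biomass_st, name = "biomass objective",
                                subsystem = "other")))
  eps_id <- NULL
  if (spec$include_eps_pathway) {
    ns_mets <- c("f6p", "g1p", "udpg", "udpgal", "udpglcr", "udpxyl", "udparab",
                 "m6p", "m1p", "gdpman", "gdpfuc", "dtdpglc", "dtdprha",
                 "utp", "udp", "gtp", "gdp", "ttp", "tdp", "ppi", "co2", "eps",
                 "sid1", "sid2")
    mets <- c(mets, lapply(ns_mets, function(m) metabolite(m, m)))
    rev <- function(id, st, gpr = "", sub = "GB", name = id)
      reaction(id, st, name = name, lower_bound = -1000, gpr = gpr, subsystem = sub)
    fwd <- function(id, st, gpr = "", sub = "GB", name = id)
      reaction(id, st, name = name, lower_bound = 0, gpr = gpr, subsystem = sub)
    rxns <- c(rxns, list(
      rev("PGI", c(g6p = -1, f6p = 1), "gPGI", "CM", "glucose-6-P isomerase"),
      rev("PGM", c(g6p = -1, g1p = 1), "gPGM", "CM", "glucose phosphomutase"),
      fwd("UGP", c(g1p = -1, utp = -1, udpg = 1, ppi = 1), "gUGP", "GB",
          "UTP-glucose pyrophosphorylase"),
      rev("GALE", c(udpg = -1, udpgal = 1), "gGALE", "GB", "UDP-glucose 4-epimerase"),
      fwd("UGDH", c(udpg = -1, udpglcr = 1), "gUGDH", "GB",
          "UDP-glucose 6-dehydrogenase"),
      fwd("UXS", c(udpglcr = -1, udpxyl = 1, co2 = 1), "gUXS", "GB",
          "UDP-glucuronate decarboxylase"),
      rev("UXE", c(udpxyl = -1, udparab = 1), "gUXE", "GB", "UDP-arabinose 4-epimerase"),
      rev("PMI", c(f6p = -1, m6p = 1), "gPMI", "CM", "mannose-6-P isomerase"),
      rev("PMM", c(m6p = -1, m1p = 1), "gPMM", "GB", "phosphomannomutase"),
      fwd("GMP", c(m1p = -1, gtp = -1, gdpman = 1, ppi = 1), "gGMP", "GB",
          "GDP-mannose pyrophosphorylase"),
      fwd("GFS", c(gdpman = -1, gdpfuc = 1), "gGMDS and gTSTA3", "GB",
          "GDP-fucose synthesis (complex)"),
      fwd("RFFH", c(g1p = -1, ttp = -1, dtdpglc = 1, ppi = 1), "gRFFH", "GB",
          "dTDP-glucose pyrophosphorylase"),
      fwd("RHS", c(dtdpglc = -1, dtdprha = 1), "gTGDS and gRFBC", "GB",
          "dTDP-rhamnose synthesis (complex)"),
      rev("NDK_U", c(udp = -1, atp = -1, utp = 1, adp = 1), "", "NM"),
      rev("NDK_G", c(gdp = -1, atp = -1, gtp = 1, adp = 1), "", "NM"),
      rev("NDK_T", c(tdp = -1, atp = -1, ttp = 1, adp = 1), "", "NM"),
      fwd("PPA", c(ppi = -1, pi = 2), "", "EM", "pyrophosphatase"),
      build_eps_reaction(default_eps_composition(), nucleotide_sugar_donors()),
      fwd("SIDA", c(g6p = -1, sid1 = 1), "gSID", "CM", "side branch step 1"),
      fwd("SIDB", c(sid1 = -1, sid2 = 1), "", "CM", "side branch step 2"),
      reaction("EX_eps", c(eps = -1), lower_bound = 0, subsystem = "ER"),
      reaction("EX_co2", c(co2 = -1), lower_bound = 0, subsystem = "ER"),
      reaction("EX_sid", c(sid2 = -1), lower_bound = 0, subsystem = "ER")))
    eps_id <- "EPS"
  }
  # isozyme pairs: replace the single gene of eligible reactions by an OR pair
  eligible <- c(if (spec$include_eps_pathway) c("GALE", "PMI"), cat_ids, "PHET")
  if (spec$n_isozyme_pairs > length(eligible))
    stop(sprintf("n_isozyme_pairs = %d exceeds the %d eligible reactions",
                 spec$n_isozyme_pairs, length(eligible)), call. = FALSE)
  paired <- eligible[seq_len(spec$n_isozyme_pairs)]
  rxns <- lapply(rxns, function(r) {
    if (r$id %in% paired) {
      base <- gpr_genes(r$gpr)[1]
      r$gpr <- sprintf("%s_1 or %s_2", base, base)
    }
    r
  })
  met_df <- do.call(rbind, mets)
  model <- metabolic_model(met_df, rxns, biomass_reaction_id = "BIOMASS",
                           eps_reaction_id = eps_id,
                           id = sprintf("toy_seed%d", spec$seed))
  media <- toy_media(model)
  # --- planted truth -------------------------------------------------------
  gene_of <- function(rid) gpr_genes(model$reactions$gpr[match(rid, model$reactions$id)])
  single_gene <- function(rid) { g <- gene_of(rid); if (length(g) == 1) g else character(0) }
  ess_growth <- c("gHK", "gPFK", "gAAS", chain_genes)
  ess_growth_ferm <- if (appendage) setdiff(ess_growth, "gAAS") else ess_growth
  # with the appendage, the 0.01 mmol/gDW/h amino-acid feed keeps a trickle
  # of growth alive when AAS is deleted, so gAAS drops out on fermentation
  ess_eps <- if (spec$include_eps_pathway) {
    unique(c(ess_growth,
             single_gene("PGI"), single_gene("PGM"), single_gene("UGP"),
             single_gene("GALE"), single_gene("UGDH"), single_gene("UXS"),
             single_gene("UXE"), single_gene("PMI"), single_gene("PMM"),
             single_gene("GMP"), gene_of("GFS"), single_gene("RFFH"),
             gene_of("RHS")))
  } else character(0)
  glc_lim <- media$minimal$uptake_limits[["EX_glc"]]
  mu_max <- glc_lim / (2 * b + a + c_atp)
  eps_max <- if (spec$include_eps_pathway) glc_lim / 3 else NA_real_
  extra_ex <- if (n_extra > 0) paste0("EX_", extra_sources) else character(0)
  carbon_calls <- data.frame(
    substrate = c("EX_glc", extra_ex, if (appendage) "EX_ino"),
    role = "carbon",
    call = c(rep("+", 1 + n_extra), if (appendage) "-"), stringsAsFactors = FALSE)
  nitrogen_calls <- if (appendage) data.frame(
    substrate = c("EX_nh4", "EX_phe", "EX_ure"), role = "nitrogen",
    call = c("+", "+", "-"), stringsAsFactors = FALSE) else data.frame(
    substrate = "EX_nh4", role = "nitrogen", call = "+", stringsAsFactors = FALSE)
  truth <- structure(list(
    essential_genes_growth = sort(ess_growth),
    essential_genes_growth_fermentation = sort(ess_growth_ferm),
    essential_genes_eps = sort(ess_eps),
    expected_phenotype_calls = rbind(carbon_calls, nitrogen_calls),
    analytic_max_growth = mu_max,
    analytic_max_eps = eps_max,
    top_overexpression_target = NA_character_,
    media = media,
    biomass_coefficients = c(aa = a, precursor = b, atp = c_atp),
    gap_metabolite = NA_character_,
    spec = spec), class = "toy_model_truth")
  # generation-time verification of the closed-form optima against FBA
  chk <- solve_fba(apply_medium(model, media$minimal), "BIOMASS")
  if (chk$status != "optimal" || abs(chk$objective_value - mu_max) > 1e-6)
    stop(sprintf("toy generator self-check failed: FBA growth %.9f vs analytic %.9f",
                 chk$objective_value, mu_max), call. = FALSE)
  if (spec$include_eps_pathway) {
    chk2 <- solve_fba(apply_medium(model, media$minimal), "EPS")
    if (chk2$status != "optimal" || abs(chk2$objective_value - eps_max) > 1e-6)
      stop("toy generator self-check failed on the EPS optimum", call. = FALSE)
    scr <- screen_targets(model, media$fermentation)
    truth$top_overexpression_target <- scr$reaction[1]
  }
  if (spec$inject_gap) {
    gapped <- inject_gap(model, seed = spec$seed)
    model <- gapped$model
    truth$gap_metabolite <- gapped$gap_metabolite
  }
  list(model = model, truth = truth)
}

#' Built-in media matched to a toy model's exchange reactions
#'
#' Builds the minimal medium (glucose 10 mmol/gDW/h plus the model's
#' inorganic exchanges, unlimited) and the fermentation medium (minimal
#' plus every amino-acid exchange the model carries, at 0.01 mmol/gDW/h)
#' from the exchanges actually present.
#'
#' @param model A `metabolic_model` using the `EX_<metabolite>` convention.
#' @param glucose_uptake Glucose cap (default 10 mmol/gDW/h).
#' @param amino_acid_uptake Per-amino-acid cap (default 0.01 mmol/gDW/h).
#' @return List with `minimal` and `fermentation` `medium_definition`s.
#' @export
toy_media <- function(model, glucose_uptake = 10, amino_acid_uptake = 0.01) {
  ex_ids <- model$reactions$id[is_exchange_reaction(model)]
  inorganic <- intersect(c("EX_nh4", "EX_pi", "EX_so4", "EX_o2", "EX_h2o", "EX_h"), ex_ids)
  aa_ex <- intersect(paste0("EX_", amino_acid_ids()), ex_ids)
  lim_min <- c(stats::setNames(glucose_uptake, "EX_glc"),
               stats::setNames(rep(1000, length(inorganic)), inorganic))
  minimal <- medium("minimal", lim_min)
  fermentation <- medium("fermentation",
                         c(lim_min, stats::setNames(rep(amino_acid_uptake, length(aa_ex)), aa_ex)))
  list(minimal = minimal, fermentation = fermentation)
}

#' Inject a dead-end gap into a model
#'
#' Picks (seeded) one internal metabolite whose consuming reactions can all
#' be removed such that exactly one new dead end appears - the metabolite
#' itself - while wild-type growth on the minimal medium stays positive,
#' and removes those consumers. Emulates the draft-reconstruction gaps that
#' curation pipelines must detect. Candidates never include the biomass or
#' EPS sink among their consumers.
#'
#' @param model A `metabolic_model`.
#' @param seed Integer seed for the candidate choice.
#' @param medium Medium used for the growth-preservation check (default:
#'   the model's minimal toy medium).
#' @return List with `model` (gapped) and `gap_metabolite` (id).
#' @export
inject_gap <- function(model, seed = 0, medium = toy_media(model)$minimal) {
  validate_model(model)
  base_dead <- find_dead_ends(model)
  exch <- is_exchange_reaction(model)
  protected <- c(model$biomass_reaction_id, model$eps_reaction_id)
  internal_mets <- setdiff(model$metabolites$id,
                           unlist(lapply(model$stoichiometry[model$reactions$id[exch]], names)))
  candidates <- list()
  for (m in internal_mets) {
    consumers <- model$reactions$id[vapply(model$reactions$id, function(rid) {
      st <- model$stoichiometry[[rid]]
      if (!m %in% names(st)) return(FALSE)
      s <- st[[m]]
      j <- match(rid, model$reactions$id)
      (s < 0 && model$reactions$upper_bound[j] > 0) ||
        (s > 0 && model$reactions$lower_bound[j] < 0)
    }, logical(1))]
    if (length(consumers) == 0 || any(consumers %in% protected)) next
    gapped <- drop_reactions(model, consumers)
    new_dead <- setdiff(find_dead_ends(gapped), base_dead)
    if (!identical(sort(new_dead), sort(m))) next
    sol <- solve_fba(apply_medium(gapped, medium, ignore_missing = TRUE),
                     model$biomass_reaction_id)
    if (sol$status != "optimal" || sol$objective_value < 1e-6) next
    candidates[[m]] <- consumers
  }
  if (length(candidates) == 0)
    stop("no candidate metabolite: every consumer-removal either cascades or kills growth",
         call. = FALSE)
  pick <- with_preserved_seed(seed, sample(names(candidates), 1))
  list(model = drop_reactions(model, candidates[[pick]]), gap_metabolite = pick)
}

drop_reactions <- function(model, rids) {
  keep <- !model$reactions$id %in% rids
  model$reactions <- model$reactions[keep, , drop = FALSE]
  rownames(model$reactions) <- NULL
  model$stoichiometry <- model$stoichiometry[model$reactions$id]
  model
}

#' Write phenotype truth tables for a toy model
#'
#' Emits the sole-source validation fixtures in the published layout
#' (`substrate`, `in_vivo`, `in_silico`), one file per role, with both
#' columns equal to the planted call (the generated truth is
#' self-consistent by construction).
#'
#' @param model A toy `metabolic_model` (used for naming only).
#' @param truth The matching `toy_model_truth`.
#' @param dir Output directory; `NULL` skips writing.
#' @return Named list of `data.frame`s (`carbon`, `nitrogen`), invisibly
#'   when writing.
#' @export
phenotype_truth_table <- function(model, truth, dir = NULL) {
  calls <- truth$expected_phenotype_calls
  out <- lapply(split(calls, calls$role), function(df) {
    data.frame(substrate = sub("^EX_", "", df$substrate),
               in_vivo = df$call, in_silico = df$call, stringsAsFactors = FALSE)
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (role in names(out)) {
      utils::write.table(out[[role]], file.path(dir, paste0("table_", role, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    return(invisible(out))
  }
  out
}
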