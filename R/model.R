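#' Create a metabolite
#'
#' @param id Unique metabolite id (non-empty string). A compartment suffix in
#'   square brackets (e.g. `"glc-D[e]"`) is treated as part of the id.
#' @param name Human-readable name; defaults to the id.
#' @param compartment Compartment label (default `"c"`).
#' @param formula Elemental composition as a Hill-style string
#'   (e.g. `"C6H12O6"`) or `NA` when unknown.
#' @param charge Integer formal charge or `NA`.
#' @return A one-row `data.frame` with the metabolite fields.
#' @export
metabolite <- function(id, name = id, compartment = "c", formula = NA_character_,
                       charge = NA_integer_) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  if (!is.na(formula)) parse_formula(formula)  # validates
  data.frame(id = id, name = name, compartment = compartment,
             formula = as.character(formula), charge = as.integer(charge),
             stringsAsFactors = FALSE)
}

#' Create a reaction
#'
#' Stoichiometric coefficients follow the FBA convention: negative =
#' consumed (substrate), positive = produced. Reversibility is encoded
#' purely through the bounds (`reversible` iff `lower_bound < 0`); units are
#' mmol/gDW/h (the biomass pseudo-reaction carries 1/h).
#'
#' @param id Unique reaction id.
#' @param stoichiometry Named numeric vector, metabolite id -> coefficient.
#' @param name Human-readable name; defaults to the id.
#' @param lower_bound,upper_bound Flux bounds; `lower_bound <= upper_bound`.
#' @param gpr GPR rule string (see [parse_gpr()]); `""` = no association.
#' @param subsystem Subsystem label. The conventional ten labels are
#'   `LM` (lipid), `AM` (amino acid), `CM` (carbohydrate), `TR` (transport),
#'   `MC` (cofactors/vitamins), `NM` (nucleotide), `EM` (energy),
#'   `GB` (glycan biosynthesis), `MT` (terpenoids/polyketides),
#'   `ER` (exchange), plus `"other"`.
#' @return A list of class `model_reaction`.
#' @export
reaction <- function(id, stoichiometry, name = id, lower_bound = 0,
                     upper_bound = 1000, gpr = "", subsystem = "other") {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  stopifnot(is.numeric(stoichiometry), length(stoichiometry) > 0,
            !is.null(names(stoichiometry)), all(nzchar(names(stoichiometry))))
  if (anyDuplicated(names(stoichiometry)))
    stop(sprintf("reaction %s: duplicated metabolite in stoichiometry", id), call. = FALSE)
  if (lower_bound > upper_bound)
    stop(sprintf("reaction %s: lower_bound > upper_bound", id), call. = FALSE)
  parse_gpr(gpr)  # validates
  structure(list(id = id, name = name, stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 gpr = if (is.na(gpr)) "" else gpr, subsystem = subsystem),
            class = "model_reaction")
}

#' Assemble a metabolic model
#'
#' @param metabolites A `data.frame` of metabolite rows (see [metabolite()]);
#'   rows may be built with `rbind`/`do.call`.
#' @param reactions A list of [reaction()] objects.
#' @param biomass_reaction_id Id of the biomass pseudo-reaction (must exist).
#' @param eps_reaction_id Optional id of the EPS sink pseudo-reaction.
#' @param genes Optional character vector of gene ids; defaults to the union
#'   of all GPR leaves.
#' @param id Model identifier string.
#' @return A list of class `metabolic_model` with components `id`,
#'   `metabolites` (data.frame), `reactions` (data.frame of scalar fields),
#'   `stoichiometry` (named list of named numeric vectors),
#'   `genes`, `biomass_reaction_id`, `eps_reaction_id`.
#' @export
metabolic_model <- function(metabolites, reactions, biomass_reaction_id,
                            eps_reaction_id = NULL, genes = NULL, id = "model") {
  if (inherits(reactions, "model_reaction")) reactions <- list(reactions)
  stopifnot(is.data.frame(metabolites), is.list(reactions))
  rxn_df <- do.call(rbind, lapply(reactions, function(r) {
    data.frame(id = r$id, name = r$name, lower_bound = r$lower_bound,
               upper_bound = r$upper_bound, gpr = r$gpr,
               subsystem = r$subsystem, stringsAsFactors = FALSE)
  }))
  stoich <- lapply(reactions, `[[`, "stoichiometry")
  names(stoich) <- rxn_df$id
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(rxn_df$gpr, gpr_genes), use.names = FALSE)))
  model <- structure(list(id = id, metabolites = metabolites, reactions = rxn_df,
                          stoichiometry = stoich, genes = genes,
                          biomass_reaction_id = biomass_reaction_id,
                          eps_reaction_id = eps_reaction_id),
                     class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, referential integrity of stoichiometries, GPR gene
#' coverage, bound ordering, and existence of the biomass reaction. Errors
#' name the offending entity.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly, if valid; otherwise an error is raised.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  if (anyDuplicated(met_ids))
    stop(sprintf("duplicate metabolite id: %s",
                 paste(unique(met_ids[duplicated(met_ids)]), collapse = ", ")), call. = FALSE)
  if (anyDuplicated(rxn_ids))
    stop(sprintf("duplicate reaction id: %s",
                 paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", ")), call. = FALSE)
  if (!identical(sort(names(model$stoichiometry)), sort(rxn_ids)))
    stop("stoichiometry list and reaction table disagree", call. = FALSE)
  for (rid in rxn_ids) {
    st <- model$stoichiometry[[rid]]
    if (length(st) == 0) stop(sprintf("reaction %s: empty stoichiometry", rid), call. = FALSE)
    missing <- setdiff(names(st), met_ids)
    if (length(missing))
      stop(sprintf("reaction %s references unknown metabolite(s): %s",
                   rid, paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- model$reactions$lower_bound > model$reactions$upper_bound
  if (any(bad))
    stop(sprintf("lower_bound > upper_bound for: %s",
                 paste(rxn_ids[bad], collapse = ", ")), call. = FALSE)
  gpr_gene_set <- unique(unlist(lapply(model$reactions$gpr, gpr_genes), use.names = FALSE))
  orphans <- setdiff(gpr_gene_set, model$genes)
  if (length(orphans))
    stop(sprintf("GPR gene(s) not in model gene set: %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  if (!model$biomass_reaction_id %in% rxn_ids)
    stop(sprintf("biomass reaction %s not found", model$biomass_reaction_id), call. = FALSE)
  if (!is.null(model$eps_reaction_id) && !model$eps_reaction_id %in% rxn_ids)
    stop(sprintf("EPS reaction %s not found", model$eps_reaction_id), call. = FALSE)
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d metabolites, %d reactions, %d genes\n",
              x$id, nrow(x$metabolites), nrow(x$reactions), length(x$genes)))
  cat(sprintf("  biomass: %s%s\n", x$biomass_reaction_id,
              if (is.null(x$eps_reaction_id)) "" else paste0(" | EPS: ", x$eps_reaction_id)))
  invisible(x)
}

#' Exchange reactions of a model
#'
#' An exchange (boundary) reaction has exactly one metabolite in its
#' stoichiometry; uptake is a negative exchange flux.
#'
#' @param model A `metabolic_model`.
#' @return Logical vector along `model$reactions`.
#' @export
is_exchange_reaction <- function(model) {
  vapply(model$stoichiometry[model$reactions$id], function(s) length(s) == 1L, logical(1))
}

#' Assemble the stoichiometric matrix S
#'
#' @param model A `metabolic_model`.
#' @return A list with `S` (sparse `dgCMatrix`, rows = metabolites, columns =
#'   reactions, dimnames set), `metabolite_index` and `reaction_index`
#'   (named integer maps, bijections onto row/column positions).
#' @examples
#' # A -> B, B -> : S = [[-1, 0], [1, -1]]
#' @export
assemble_stoichiometric_matrix <- function(model) {
  validate_model(model)
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  mi <- stats::setNames(seq_along(met_ids), met_ids)
  ri <- stats::setNames(seq_along(rxn_ids), rxn_ids)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rxn_ids)) {
    st <- model$stoichiometry[[rxn_ids[j]]]
    ii <- c(ii, mi[names(st)]); jj <- c(jj, rep.int(j, length(st))); xx <- c(xx, unname(st))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(met_ids), length(rxn_ids)),
                            dimnames = list(met_ids, rxn_ids))
  list(S = S, metabolite_index = mi, reaction_index = ri)
}

#' Parse an elemental formula string
#'
#' @param formula Hill-style formula, e.g. `"C6H12O6"`.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  f <- trimws(formula)
  if (!nzchar(f)) return(stats::setNames(integer(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  pieces <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
  if (sum(nchar(pieces)) != nchar(f))
    stop(sprintf("cannot parse formula '%s'", formula), call. = FALSE)
  el <- sub("[0-9]*$", "", pieces)
  ct <- sub("^[A-Za-z]+", "", pieces)
  ct <- ifelse(nzchar(ct), as.integer(ct), 1L)
  out <- tapply(ct, el, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Check elemental and charge balance of every reaction
#'
#' Exchange reactions, the biomass reaction, the EPS sink and any reaction
#' id matched by `exempt_pattern` are intentionally unbalanced
#' pseudo-reactions and are reported as `"exempt"`. Reactions in which no
#' participating metabolite carries a formula are `"unverifiable"` (missing
#' annotation is not evidence of error). A reaction is `"balanced"` iff for
#' every element the coefficient-weighted counts sum to zero and the
#' coefficient-weighted charges sum to zero.
#'
#' @param model A `metabolic_model`.
#' @param exempt_pattern Regex of additionally exempt reaction ids
#'   (default: demand/sink prefixes).
#' @param tol Numeric tolerance on the weighted sums.
#' @return A `data.frame` with columns `reaction_id`, `status`
#'   (`balanced`/`imbalanced`/`unverifiable`/`exempt`) and `detail`
#'   (per-element net excess for imbalanced rows).
#' @export
check_mass_charge_balance <- function(model, exempt_pattern = "^(DM_|SK_)", tol = 1e-9) {
  validate_model(model)
  met <- model$metabolites
  formulas <- stats::setNames(met$formula, met$id)
  charges <- stats::setNames(met$charge, met$id)
  exch <- is_exchange_reaction(model)
  out <- vector("list", nrow(model$reactions))
  for (j in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[j]
    if (exch[j] || rid %in% c(model$biomass_reaction_id, model$eps_reaction_id) ||
        grepl(exempt_pattern, rid)) {
      out[[j]] <- data.frame(reaction_id = rid, status = "exempt", detail = "")
      next
    }
    st <- model$stoichiometry[[rid]]
    fms <- formulas[names(st)]
    if (all(is.na(fms))) {
      out[[j]] <- data.frame(reaction_id = rid, status = "unverifiable",
                             detail = "no participating metabolite has a formula")
      next
    }
    if (anyNA(fms)) {
      out[[j]] <- data.frame(reaction_id = rid, status = "unverifiable",
                             detail = sprintf("missing formula: %s",
                                              paste(names(st)[is.na(fms)], collapse = ", ")))
      next
    }
    counts <- lapply(fms, parse_formula)
    elements <- unique(unlist(lapply(counts, names), use.names = FALSE))
    net <- vapply(elements, function(e) {
      sum(unname(st) * vapply(counts, function(ct) {
        if (e %in% names(ct)) as.numeric(ct[[e]]) else 0
      }, numeric(1)))
    }, numeric(1))
    chg <- charges[names(st)]
    net_charge <- if (anyNA(chg)) NA_real_ else sum(unname(st) * as.numeric(chg))
    bad_el <- elements[abs(net) > tol]
    bad_chg <- !is.na(net_charge) && abs(net_charge) > tol
    if (length(bad_el) == 0 && !bad_chg) {
      out[[j]] <- data.frame(reaction_id = rid, status = "balanced", detail = "")
    } else {
      det <- paste(c(sprintf("%s: %+g", bad_el, net[bad_el]),
                     if (bad_chg) sprintf("charge: %+g", net_charge)), collapse = "; ")
      out[[j]] <- data.frame(reaction_id = rid, status = "imbalanced", detail = det)
    }
  }
  do.call(rbind, out)
}

#' Find dead-end metabolites
#'
#' A metabolite is a dead end iff, given the bounds/reversibility of the
#' reactions it participates in, no reaction can produce it or none can
#' consume it. A reaction with coefficient `s` can produce the metabolite
#' when `s > 0 & upper_bound > 0` or `s < 0 & lower_bound < 0`, and consume
#' it in the mirror cases. Exchange reactions count as both producer and
#' consumer of their single metabolite (the boundary can always absorb or
#' supply it once opened).
#'
#' @param model A `metabolic_model`.
#' @return Character vector of dead-end metabolite ids (possibly empty).
#' @export
find_dead_ends <- function(model) {
  validate_model(model)
  exch <- stats::setNames(is_exchange_reaction(model), model$reactions$id)
  lb <- stats::setNames(model$reactions$lower_bound, model$reactions$id)
  ub <- stats::setNames(model$reactions$upper_bound, model$reactions$id)
  produced <- consumed <- stats::setNames(logical(nrow(model$metabolites)), model$metabolites$id)
  for (rid in model$reactions$id) {
    st <- model$stoichiometry[[rid]]
    if (exch[[rid]]) {
      produced[names(st)] <- TRUE
      consumed[names(st)] <- TRUE
      next
    }
    for (m in names(st)) {
      s <- st[[m]]
      if ((s > 0 && ub[[rid]] > 0) || (s < 0 && lb[[rid]] < 0)) produced[[m]] <- TRUE
      if ((s < 0 && ub[[rid]] > 0) || (s > 0 && lb[[rid]] < 0)) consumed[[m]] <- TRUE
    }
  }
  names(produced)[!(produced & consumed)]
}

#' Set flux bounds of one reaction
#'
#' @param model A `metabolic_model`.
#' @param reaction_id Reaction id.
#' @param lower_bound,upper_bound New bounds; `NULL` leaves a bound untouched.
#' @return The modified model.
#' @export
set_reaction_bounds <- function(model, reaction_id, lower_bound = NULL, upper_bound = NULL) {
  j <- match(reaction_id, model$reactions$id)
  if (is.na(j)) stop(sprintf("unknown reaction: %s", reaction_id), call. = FALSE)
  if (!is.null(lower_bound)) model$reactions$lower_bound[j] <- lower_bound
  if (!is.null(upper_bound)) model$reactions$upper_bound[j] <- upper_bound
  if (model$reactions$lower_bound[j] > model$reactions$upper_bound[j])
    stop(sprintf("reaction %s: lower_bound > upper_bound", reaction_id), call. = FALSE)
  model
}
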