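#' Define a growth medium
#'
#' A medium is a set of maximal uptake rates over exchange reactions.
#' An uptake limit `u >= 0` (mmol/gDW/h) means the metabolite may be
#' consumed at up to that rate: applying the medium sets the exchange lower
#' bound to `-u` and closes (lower bound 0) every exchange the medium does
#' not list. Secretion stays open at `secretion_cap` for all exchanges when
#' `unconstrained_secretion` is `TRUE`.
#'
#' @param name Medium name.
#' @param uptake_limits Named non-negative numeric vector, exchange
#'   reaction id -> maximal uptake rate.
#' @param carbon_source Exchange id of the designated carbon source
#'   (swapped out in sole-carbon-source tests).
#' @param nitrogen_source Exchange id of the designated nitrogen source.
#' @param unconstrained_secretion Keep all secretion directions open
#'   (default `TRUE`).
#' @param secretion_cap Upper bound applied to exchanges (default 1000).
#' @return A list of class `medium_definition`.
#' @export
medium <- function(name, uptake_limits, carbon_source = "EX_glc",
                   nitrogen_source = "EX_nh4", unconstrained_secretion = TRUE,
                   secretion_cap = 1000) {
  stopifnot(is.numeric(uptake_limits), !is.null(names(uptake_limits)))
  if (any(uptake_limits < 0))
    stop(sprintf("negative uptake limit for: %s",
                 paste(names(uptake_limits)[uptake_limits < 0], collapse = ", ")),
         call. = FALSE)
  structure(list(name = name, uptake_limits = uptake_limits,
                 carbon_source = carbon_source, nitrogen_source = nitrogen_source,
                 unconstrained_secretion = isTRUE(unconstrained_secretion),
                 secretion_cap = secretion_cap),
            class = "medium_definition")
}

#' @export
print.medium_definition <- function(x, ...) {
  cat(sprintf("<medium_definition> %s: %d open uptakes (C: %s, N: %s)\n",
              x$name, length(x$uptake_limits), x$carbon_source, x$nitrogen_source))
  invisible(x)
}

# The twenty proteinogenic amino acids, in the short ids used by the
# built-in exchange naming convention EX_<metabolite>.
amino_acid_ids <- function() {
  c("ala", "arg", "asn", "asp", "cys", "gln", "glu", "gly", "his", "ile",
    "leu", "lys", "met", "phe", "pro", "ser", "thr", "trp", "tyr", "val")
}

#' Load a medium definition from a preset, list or YAML/JSON file
#'
#' Two presets ship with the package:
#' * `"minimal"` - glucose (10 mmol/gDW/h) plus the inorganic nutrient
#'   exchanges (ammonium, phosphate, sulfate, oxygen, water, protons); no
#'   amino-acid uptake.
#' * `"fermentation"` - the minimal medium plus all 20 amino-acid exchanges,
#'   each capped at 0.01 mmol/gDW/h.
#'
#' A list/file config has fields `name`, optional `base` (preset to extend),
#' `uptake_limits` (mapping exchange id -> limit; overrides the base),
#' and optional `carbon_source` / `nitrogen_source`.
#'
#' @param config Preset name, a list, or a path to a YAML/JSON file.
#' @return A `medium_definition`.
#' @examples
#' load_medium("fermentation")
#' load_medium(list(name = "glc-lim", base = "minimal",
#'                  uptake_limits = list(EX_glc = 0.506)))
#' @export
load_medium <- function(config) {
  if (inherits(config, "medium_definition")) return(config)
  if (is.character(config) && length(config) == 1 && file.exists(config)) {
    config <- yaml::read_yaml(config)
  }
  if (is.character(config) && length(config) == 1) {
    return(medium_preset(config))
  }
  stopifnot(is.list(config))
  base <- if (!is.null(config$base)) medium_preset(config$base) else
    medium(name = config$name %||% "custom", uptake_limits = stats::setNames(numeric(0), character(0)))
  limits <- base$uptake_limits
  if (!is.null(config$uptake_limits)) {
    upd <- unlist(config$uptake_limits)
    if (any(upd < 0))
      stop(sprintf("negative uptake limit for: %s",
                   paste(names(upd)[upd < 0], collapse = ", ")), call. = FALSE)
    limits[names(upd)] <- upd
  }
  medium(name = config$name %||% base$name, uptake_limits = limits,
         carbon_source = config$carbon_source %||% base$carbon_source,
         nitrogen_source = config$nitrogen_source %||% base$nitrogen_source,
         unconstrained_secretion = config$unconstrained_secretion %||% base$unconstrained_secretion,
         secretion_cap = config$secretion_cap %||% base$secretion_cap)
}

medium_preset <- function(name) {
  inorganic <- c(EX_nh4 = 1000, EX_pi = 1000, EX_so4 = 1000, EX_o2 = 1000,
                 EX_h2o = 1000, EX_h = 1000)
  if (identical(name, "minimal")) {
    return(medium("minimal", c(EX_glc = 10, inorganic)))
  }
  if (identical(name, "fermentation")) {
    aas <- stats::setNames(rep(0.01, 20), paste0("EX_", amino_acid_ids()))
    return(medium("fermentation", c(EX_glc = 10, inorganic, aas)))
  }
  stop(sprintf("unknown medium preset '%s' (available: minimal, fermentation)", name),
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a medium to a model
#'
#' Every exchange reaction listed in the medium gets lower bound
#' `-uptake_limit`; every unlisted exchange is closed for uptake (lower
#' bound 0). Non-exchange reactions are untouched. Exchanges named by the
#' medium but absent from the model are an error unless `ignore_missing`
#' (skips them; a toy model need not carry all 20 amino-acid exchanges) or
#' `add_missing` (creates the exchange when the bare metabolite exists).
#'
#' @param model A `metabolic_model`.
#' @param medium A `medium_definition` or anything [load_medium()] accepts.
#' @param ignore_missing Skip medium entries with no matching exchange.
#' @param add_missing Auto-create missing exchanges for existing metabolites.
#' @return The constrained model.
#' @export
apply_medium <- function(model, medium, ignore_missing = FALSE, add_missing = FALSE) {
  medium <- load_medium(medium)
  validate_model(model)
  exch <- is_exchange_reaction(model)
  rxn_ids <- model$reactions$id
  for (ex_id in names(medium$uptake_limits)) {
    j <- match(ex_id, rxn_ids)
    if (is.na(j)) {
      met_id <- sub("^EX_", "", ex_id)
      if (add_missing && met_id %in% model$metabolites$id) {
        new_rxn <- reaction(ex_id, stats::setNames(-1, met_id),
                            lower_bound = 0, upper_bound = medium$secretion_cap,
                            subsystem = "ER")
        model$reactions <- rbind(model$reactions, data.frame(
          id = new_rxn$id, name = new_rxn$name, lower_bound = new_rxn$lower_bound,
          upper_bound = new_rxn$upper_bound, gpr = "", subsystem = "ER",
          stringsAsFactors = FALSE))
        model$stoichiometry[[ex_id]] <- new_rxn$stoichiometry
        rxn_ids <- model$reactions$id
        exch <- is_exchange_reaction(model)
      } else if (ignore_missing) {
        next
      } else {
        stop(sprintf("medium %s names exchange '%s' which is not in the model",
                     medium$name, ex_id), call. = FALSE)
      }
    } else if (!exch[j]) {
      stop(sprintf("medium %s names '%s', which is not an exchange reaction",
                   medium$name, ex_id), call. = FALSE)
    }
  }
  exch <- is_exchange_reaction(model)
  for (j in which(exch)) {
    rid <- model$reactions$id[j]
    has <- rid %in% names(medium$uptake_limits)
    model$reactions$lower_bound[j] <- if (has) -medium$uptake_limits[[rid]] else 0
    if (medium$unconstrained_secretion)
      model$reactions$upper_bound[j] <- medium$secretion_cap
  }
  model
}
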