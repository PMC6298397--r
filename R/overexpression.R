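#' Overexpression record arithmetic
#'
#' The selection score of the overexpression screen is the product of the
#' specific biomass and product fold changes between the overexpression and
#' wild-type simulations:
#' `f_PH = f_biomass * f_EPS = (V_biomass,oe / V_biomass,wt) * (V_EPS,oe / V_EPS,wt)`.
#' A target is selected iff it yields strictly higher EPS production and
#' `f_PH > 1`.
#'
#' @param reaction Reaction id of the amplified target.
#' @param fold Amplification factor (>= 1).
#' @param V_biomass_wt,V_biomass_oe Wild-type / overexpression growth rate (1/h).
#' @param V_eps_wt,V_eps_oe Wild-type / overexpression EPS rate (mmol/gDW/h).
#' @param status Solver status of the overexpression simulation.
#' @return One-row `data.frame` with the fold ratios `f_biomass`, `f_eps`,
#'   `f_ph` (`f_ph = f_biomass * f_eps` exactly, by construction) and the
#'   `selected` flag.
#' @examples
#' # fold change implied by an EPS rate rising from 0.005 to 0.0133 mmol/gDW/h
#' overexpression_record("PGM", 2, 1, 1, 0.005, 0.0133)$f_eps  # 2.66
#' @export
overexpression_record <- function(reaction, fold, V_biomass_wt, V_biomass_oe,
                                  V_eps_wt, V_eps_oe, status = "optimal") {
  f_biomass <- V_biomass_oe / V_biomass_wt
  f_eps <- V_eps_oe / V_eps_wt
  f_ph <- f_biomass * f_eps
  data.frame(reaction = reaction, fold = fold,
             V_biomass_wt = V_biomass_wt, V_biomass_oe = V_biomass_oe,
             V_eps_wt = V_eps_wt, V_eps_oe = V_eps_oe,
             f_biomass = f_biomass, f_eps = f_eps, f_ph = f_ph,
             selected = !is.na(f_ph) && status == "optimal" &&
               V_eps_oe > V_eps_wt && f_ph > 1,
             status = status, stringsAsFactors = FALSE)
}

#' Impose amplified flux on a reaction
#'
#' Simulates gene overexpression by forcing the reaction to carry at least
#' `fold` times its wild-type flux, preserving direction: for positive
#' `wt_flux` the lower bound is raised to `fold * wt_flux`; for negative
#' `wt_flux` the upper bound is lowered to `fold * wt_flux`. Only
#' non-zero-flux reactions are meaningful candidates; a (near-)zero
#' `wt_flux` is an error here and a skip in [screen_targets()].
#'
#' @param model A `metabolic_model`.
#' @param reaction_id Target reaction id.
#' @param wt_flux Wild-type (reference) flux of the reaction.
#' @param fold Amplification factor (default 2).
#' @param zero_tol Magnitude below which `wt_flux` counts as zero.
#' @return The perturbed model.
#' @export
overexpress_reaction <- function(model, reaction_id, wt_flux, fold = 2,
                                 zero_tol = 1e-6) {
  if (abs(wt_flux) <= zero_tol)
    stop(sprintf("reaction %s carries (near-)zero wild-type flux; not a candidate",
                 reaction_id), call. = FALSE)
  j <- match(reaction_id, model$reactions$id)
  if (is.na(j)) stop(sprintf("unknown reaction: %s", reaction_id), call. = FALSE)
  target <- fold * wt_flux
  if (wt_flux > 0) {
    model$reactions$lower_bound[j] <- target
    if (model$reactions$upper_bound[j] < target)
      model$reactions$upper_bound[j] <- target
  } else {
    model$reactions$upper_bound[j] <- target
    if (model$reactions$lower_bound[j] > target)
      model$reactions$lower_bound[j] <- target
  }
  model
}

#' MOMA overexpression screen ranked by f_PH
#'
#' The five-step screening algorithm for product-enhancing amplification
#' targets: (i) a minimum product (EPS) flux equal to `phi` times the
#' product's FBA maximum under the medium is imposed on the model; (ii) the
#' wild-type reference flux distribution is computed on that model by
#' parsimonious FBA with the biomass objective; (iii) each non-zero-flux
#' reaction (exchanges, the biomass and the product sink excepted) is
#' amplified `fold`-fold with [overexpress_reaction()]; (iv) the perturbed
#' flux state is predicted by [solve_moma()] against the reference; (v) the
#' biomass and product rates are read off the MOMA solution, the fold
#' ratios and `f_PH` are formed, and targets with higher product flux and
#' `f_PH > 1` are selected. Results are sorted by decreasing `f_ph`, ties
#' by reaction id, so repeated runs are identical.
#'
#' @param model A `metabolic_model` with a product (EPS) reaction.
#' @param medium Medium for the screen (the study design uses the
#'   fermentation medium).
#' @param eps_id Product reaction id (default: the model's EPS reaction).
#' @param biomass_id Biomass reaction id.
#' @param fold Amplification factor (default 2).
#' @param phi Fraction of the product's FBA maximum imposed as its minimum
#'   flux in step (i) (default 0.1).
#' @param candidates Optional character vector restricting step (iii).
#' @return A `data.frame` of [overexpression_record()] rows with an extra
#'   `genes` column (GPR genes behind each target; isozymes all reported),
#'   ranked by `f_ph`. Attributes: `reference` (the wild-type
#'   `flux_distribution`), `eps_imposed` (the step-(i) floor).
#' @export
screen_targets <- function(model, medium, eps_id = model$eps_reaction_id,
                           biomass_id = model$biomass_reaction_id, fold = 2,
                           phi = 0.1, candidates = NULL) {
  if (is.null(eps_id)) stop("model has no EPS reaction", call. = FALSE)
  model <- apply_medium(model, medium, ignore_missing = TRUE)
  eps_max <- solve_fba(model, eps_id)
  if (eps_max$status != "optimal" || eps_max$objective_value <= 0)
    stop("product flux cannot be imposed: EPS FBA maximum is not positive",
         call. = FALSE)
  eps_floor <- phi * eps_max$objective_value
  model <- set_reaction_bounds(model, eps_id, lower_bound = eps_floor)
  reference <- parsimonious_reference(model, biomass_id)
  if (reference$status != "optimal")
    stop("wild-type reference FBA infeasible under the imposed product flux",
         call. = FALSE)
  V_biomass_wt <- reference$fluxes[[biomass_id]]
  V_eps_wt <- reference$fluxes[[eps_id]]
  exch <- is_exchange_reaction(model)
  if (is.null(candidates)) {
    candidates <- model$reactions$id[!exch &
                                     !model$reactions$id %in% c(biomass_id, eps_id)]
  }
  rows <- lapply(candidates, function(rid) {
    wt_flux <- reference$fluxes[[rid]]
    if (abs(wt_flux) <= 1e-6) {
      rec <- overexpression_record(rid, fold, V_biomass_wt, NA_real_,
                                   V_eps_wt, NA_real_, status = "skipped_zero_flux")
      rec$selected <- FALSE
      return(rec)
    }
    pert <- overexpress_reaction(model, rid, wt_flux, fold)
    sol <- solve_moma(pert, reference)
    if (sol$status != "optimal") {
      rec <- overexpression_record(rid, fold, V_biomass_wt, NA_real_,
                                   V_eps_wt, NA_real_, status = "infeasible")
      rec$selected <- FALSE
      return(rec)
    }
    overexpression_record(rid, fold, V_biomass_wt, sol$fluxes[[biomass_id]],
                          V_eps_wt, sol$fluxes[[eps_id]])
  })
  out <- do.call(rbind, rows)
  out$genes <- vapply(out$reaction, function(rid) {
    paste(gpr_genes(model$reactions$gpr[match(rid, model$reactions$id)]),
          collapse = ",")
  }, character(1))
  rank_key <- round(ifelse(is.na(out$f_ph), -Inf, out$f_ph), 8)  # QP dust != a rank
  out <- out[order(-rank_key, out$reaction), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  attr(out, "eps_imposed") <- eps_floor
  out
}
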