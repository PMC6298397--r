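#' Single-gene-deletion essentiality screen
#'
#' For each gene, every GPR is re-evaluated with that gene knocked out;
#' reactions whose rule turns false get bounds `[0, 0]`, FBA is re-solved,
#' and the gene is called essential when the objective drops below
#' `threshold` (the numeric floor standing in for "deletion results in zero
#' growth") or the problem becomes infeasible. Genes appearing in no GPR
#' never disable a reaction and inherit the wild-type objective exactly.
#'
#' @param model A `metabolic_model`.
#' @param medium Optional medium (anything [load_medium()] accepts),
#'   applied before the screen.
#' @param objective_id Objective reaction id (default: biomass).
#' @param genes Genes to screen (default: all model genes).
#' @param threshold Essentiality floor on the objective (default `1e-6`,
#'   safely above LP tolerance).
#' @param ignore_missing_exchanges Passed to [apply_medium()].
#' @return A `data.frame` with one row per gene: `gene`,
#'   `disabled_reactions` (comma-joined ids), `objective_value`,
#'   `ratio_to_wt`, `essential`. The wild-type objective is attached as
#'   attribute `wt_objective`.
#' @export
single_gene_deletion <- function(model, medium = NULL,
                                 objective_id = model$biomass_reaction_id,
                                 genes = model$genes, threshold = 1e-6,
                                 ignore_missing_exchanges = FALSE) {
  if (!is.null(medium))
    model <- apply_medium(model, medium, ignore_missing = ignore_missing_exchanges)
  wt <- solve_fba(model, objective_id)
  if (wt$status != "optimal")
    stop(sprintf("wild-type FBA is %s; cannot run the deletion screen", wt$status),
         call. = FALSE)
  rules <- lapply(model$reactions$gpr, parse_gpr)
  rule_genes <- lapply(rules, gpr_genes)
  rows <- vector("list", length(genes))
  for (k in seq_along(genes)) {
    g <- genes[k]
    affected <- which(vapply(seq_along(rules), function(j) {
      g %in% rule_genes[[j]] && !evaluate_gpr(rules[[j]], knocked_out = g)
    }, logical(1)))
    if (length(affected) == 0) {
      obj <- wt$objective_value
    } else {
      mut <- model
      mut$reactions$lower_bound[affected] <- 0
      mut$reactions$upper_bound[affected] <- 0
      sol <- solve_fba(mut, objective_id)
      obj <- if (sol$status == "optimal") sol$objective_value else NA_real_
    }
    rows[[k]] <- data.frame(
      gene = g,
      disabled_reactions = paste(model$reactions$id[affected], collapse = ","),
      objective_value = obj,
      ratio_to_wt = if (abs(wt$objective_value) > .Machine$double.eps) obj / wt$objective_value else NA_real_,
      essential = is.na(obj) || obj < threshold,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "wt_objective") <- wt$objective_value
  attr(out, "objective_id") <- objective_id
  out
}

#' Gene essentiality for product synthesis under a growth constraint
#'
#' Before screening for product (e.g. EPS) essentiality the biomass flux is
#' constrained to a fraction of its wild-type optimum, so that "essential
#' for the product" is judged in cells that still grow. A gene is essential
#' when the product optimum falls below `threshold` or the constrained
#' problem is infeasible.
#'
#' @inheritParams single_gene_deletion
#' @param product_objective_id Product sink reaction id (default: the EPS
#'   reaction).
#' @param biomass_fraction Fraction of the wild-type growth optimum imposed
#'   as a lower bound on biomass (default 0.5; 0 reduces to plain product
#'   essentiality).
#' @return As [single_gene_deletion()], with attribute `biomass_floor`.
#' @export
essential_for_product <- function(model, medium = NULL,
                                  product_objective_id = model$eps_reaction_id,
                                  biomass_fraction = 0.5, genes = model$genes,
                                  threshold = 1e-6, ignore_missing_exchanges = FALSE) {
  if (is.null(product_objective_id))
    stop("model has no product (EPS) reaction; set product_objective_id", call. = FALSE)
  if (!is.null(medium))
    model <- apply_medium(model, medium, ignore_missing = ignore_missing_exchanges)
  mu <- solve_fba(model, model$biomass_reaction_id)
  if (mu$status != "optimal" || mu$objective_value <= 0)
    stop("wild-type growth optimum must be positive before the product screen",
         call. = FALSE)
  floor_mu <- biomass_fraction * mu$objective_value
  model <- set_reaction_bounds(model, model$biomass_reaction_id, lower_bound = floor_mu)
  out <- single_gene_deletion(model, medium = NULL,
                              objective_id = product_objective_id,
                              genes = genes, threshold = threshold)
  attr(out, "biomass_floor") <- floor_mu
  out
}

#' Subsystem breakdown of essential genes
#'
#' Each essential gene is assigned to a single subsystem by majority vote
#' over the subsystems of the reactions its GPR participates in (ties break
#' lexicographically), so the percentages partition the essential set and
#' sum to 100.
#'
#' @param records Output of [single_gene_deletion()] or
#'   [essential_for_product()].
#' @param model The model the records came from.
#' @return Named numeric vector: subsystem -> percentage of essential genes.
#' @export
subsystem_percentages <- function(records, model) {
  ess <- records$gene[records$essential]
  if (length(ess) == 0) return(stats::setNames(numeric(0), character(0)))
  rule_genes <- lapply(model$reactions$gpr, gpr_genes)
  assign_one <- function(g) {
    subs <- model$reactions$subsystem[vapply(rule_genes, function(gl) g %in% gl, logical(1))]
    if (length(subs) == 0) return("other")
    tab <- table(subs)
    names(tab)[order(-tab, names(tab))][1]   # majority, ties lexicographic
  }
  assigned <- vapply(ess, assign_one, character(1))
  tab <- table(assigned)
  pct <- 100 * as.numeric(tab) / length(ess)
  stats::setNames(pct, names(tab))
}
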