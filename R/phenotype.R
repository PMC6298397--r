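#' Growth call on a sole carbon or nitrogen source
#'
#' Rebuilds the base medium with the designated source of the tested role
#' removed and the tested substrate opened in its place (carbon tests keep
#' the inorganic nitrogen source; nitrogen tests keep the carbon source),
#' runs FBA on biomass, and calls `"+"` iff the growth rate exceeds
#' `threshold`. A substrate whose exchange reaction is absent from the
#' model is `"untestable"` - surfaced distinctly from `"-"`.
#'
#' @param model A `metabolic_model`.
#' @param base_medium Medium to modify (anything [load_medium()] accepts).
#' @param substrate_exchange Exchange reaction id of the tested substrate.
#' @param role `"carbon"` or `"nitrogen"`.
#' @param uptake Uptake limit for the tested substrate; defaults to the
#'   base medium's limit for the replaced source (qualitative calls are
#'   threshold-based and insensitive to this cap).
#' @param threshold Growth-call floor in 1/h (default `1e-6`).
#' @return One-row `data.frame`: `substrate`, `role`, `call`
#'   (`"+"`, `"-"` or `"untestable"`), `growth_rate`.
#' @export
sole_source_call <- function(model, base_medium, substrate_exchange,
                             role = c("carbon", "nitrogen"), uptake = NULL,
                             threshold = 1e-6) {
  role <- match.arg(role)
  base_medium <- load_medium(base_medium)
  replaced <- if (role == "carbon") base_medium$carbon_source else base_medium$nitrogen_source
  limits <- base_medium$uptake_limits
  if (is.null(uptake)) {
    uptake <- if (replaced %in% names(limits)) limits[[replaced]] else 10
  }
  limits <- limits[setdiff(names(limits), replaced)]
  if (!substrate_exchange %in% model$reactions$id) {
    return(data.frame(substrate = substrate_exchange, role = role,
                      call = "untestable", growth_rate = NA_real_,
                      stringsAsFactors = FALSE))
  }
  limits[substrate_exchange] <- uptake
  test_medium <- medium(paste0(base_medium$name, "+", substrate_exchange), limits,
                        carbon_source = if (role == "carbon") substrate_exchange else base_medium$carbon_source,
                        nitrogen_source = if (role == "nitrogen") substrate_exchange else base_medium$nitrogen_source,
                        unconstrained_secretion = base_medium$unconstrained_secretion,
                        secretion_cap = base_medium$secretion_cap)
  sol <- solve_fba(apply_medium(model, test_medium, ignore_missing = TRUE),
                   model$biomass_reaction_id)
  rate <- if (sol$status == "optimal") sol$objective_value else 0
  data.frame(substrate = substrate_exchange, role = role,
             call = if (rate > threshold) "+" else "-",
             growth_rate = rate, stringsAsFactors = FALSE)
}

#' Phenotype matching rate
#'
#' Percentage of substrates on which the in vivo and in silico growth
#' calls agree, reported to one decimal. Accepts `+`/`-` in ASCII or the
#' typographic minus and is symmetric in its arguments.
#'
#' @param in_vivo,in_silico Equal-length character vectors of calls,
#'   aligned by substrate.
#' @return Percentage (one decimal).
#' @examples
#' phenotype_matching_rate(c("+", "-", "+"), c("+", "+", "+"))  # 66.7
#' @export
phenotype_matching_rate <- function(in_vivo, in_silico) {
  a <- normalize_call(in_vivo); b <- normalize_call(in_silico)
  if (length(a) != length(b))
    stop(sprintf("call vectors differ in length (%d vs %d)", length(a), length(b)),
         call. = FALSE)
  if (length(a) == 0) stop("empty call vectors", call. = FALSE)
  round(100 * sum(a == b) / length(a), 1)
}

normalize_call <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("−", "–")] <- "-"
  bad <- !x %in% c("+", "-")
  if (any(bad))
    stop(sprintf("invalid growth call(s): %s", paste(unique(x[bad]), collapse = ", ")),
         call. = FALSE)
  x
}

#' Read a phenotype truth table
#'
#' Tab-delimited with columns `substrate`, `in_vivo`, `in_silico` (the
#' layout of published sole-source validation tables).
#'
#' @param path File path.
#' @return A `data.frame`.
#' @export
read_phenotype_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                           quote = "", fileEncoding = "UTF-8")
  need <- c("substrate", "in_vivo", "in_silico")
  if (!all(need %in% names(tab)))
    stop(sprintf("phenotype table %s must have columns: %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  tab$in_vivo <- normalize_call(tab$in_vivo)
  tab$in_silico <- normalize_call(tab$in_silico)
  tab
}

#' Amino-acid supplementation scan
#'
#' For each supplement, compares a baseline run on the given medium with a
#' run on the medium plus that supplement opened at `uptake` mmol/gDW/h,
#' for both the biomass and the product (EPS) objectives, and records
#' absolute rates and percent increases against the same baseline. Since a
#' supplement only relaxes one uptake bound, LP monotonicity guarantees
#' every percent increase is non-negative up to solver tolerance. The
#' product objective is maximized without a growth-coupling constraint
#' unless `biomass_fraction` is set, in which case biomass is floored at
#' that fraction of the medium's growth optimum first.
#'
#' @param model A `metabolic_model` with an EPS reaction.
#' @param medium Baseline medium.
#' @param supplements Character vector of exchange reaction ids.
#' @param uptake Uptake limit per supplement (default 0.01 mmol/gDW/h).
#' @param biomass_fraction Optional growth coupling for the product
#'   objective (default `NULL`: uncoupled).
#' @param threshold Relative floor below which a baseline rate is treated
#'   as zero when forming percentages.
#' @return A `data.frame`, one row per supplement: `supplement`,
#'   `biomass_rate`, `eps_rate`, `pct_increase_biomass`,
#'   `pct_increase_eps`, `status` (`"ok"` or `"untestable"`), sorted by
#'   decreasing `pct_increase_eps`.
#' @export
supplementation_scan <- function(model, medium, supplements, uptake = 0.01,
                                 biomass_fraction = NULL, threshold = 1e-9) {
  medium <- load_medium(medium)
  if (is.null(model$eps_reaction_id))
    stop("model has no EPS reaction; build one first", call. = FALSE)
  base_model <- apply_medium(model, medium, ignore_missing = TRUE)
  if (!is.null(biomass_fraction)) {
    mu <- solve_fba(base_model, model$biomass_reaction_id)
    if (mu$status != "optimal") stop("baseline growth FBA infeasible", call. = FALSE)
    base_model <- set_reaction_bounds(base_model, model$biomass_reaction_id,
                                      lower_bound = biomass_fraction * mu$objective_value)
  }
  run_pair <- function(mod) {
    b <- solve_fba(mod, model$biomass_reaction_id)
    e <- solve_fba(mod, model$eps_reaction_id)
    c(biomass = if (b$status == "optimal") b$objective_value else NA_real_,
      eps = if (e$status == "optimal") e$objective_value else NA_real_)
  }
  base <- run_pair(base_model)
  pct <- function(new, old) {
    if (is.na(new) || is.na(old)) return(NA_real_)
    if (abs(old) < threshold) return(if (new > threshold) Inf else 0)
    100 * (new - old) / old
  }
  rows <- lapply(supplements, function(ex) {
    if (!ex %in% model$reactions$id) {
      return(data.frame(supplement = ex, biomass_rate = NA_real_, eps_rate = NA_real_,
                        pct_increase_biomass = NA_real_, pct_increase_eps = NA_real_,
                        status = "untestable", stringsAsFactors = FALSE))
    }
    j <- match(ex, base_model$reactions$id)
    mod <- base_model
    mod$reactions$lower_bound[j] <- min(mod$reactions$lower_bound[j], -uptake)
    rates <- run_pair(mod)
    data.frame(supplement = ex,
               biomass_rate = rates[["biomass"]], eps_rate = rates[["eps"]],
               pct_increase_biomass = pct(rates[["biomass"]], base[["biomass"]]),
               pct_increase_eps = pct(rates[["eps"]], base[["eps"]]),
               status = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.na(out$pct_increase_eps), -Inf, out$pct_increase_eps),
                   out$supplement), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "baseline") <- base
  out
}
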