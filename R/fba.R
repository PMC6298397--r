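#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux through an objective reaction over the
#' steady-state flux polytope `{v : S v = 0, lb <= v <= ub}` and returns an
#' optimal vertex. Infeasibility is propagated in the `status` field, never
#' silently reported as zero growth.
#'
#' @param model A `metabolic_model`.
#' @param objective_id Objective reaction id (default: the biomass reaction).
#' @param direction `"max"` (default) or `"min"`.
#' @return A `flux_distribution`: list with `fluxes` (named numeric over all
#'   reactions), `objective_id`, `objective_value` and `status`
#'   (`"optimal"` or `"infeasible"`).
#' @export
solve_fba <- function(model, objective_id = model$biomass_reaction_id,
                      direction = c("max", "min")) {
  direction <- match.arg(direction)
  validate_model(model)
  if (!objective_id %in% model$reactions$id)
    stop(sprintf("objective reaction '%s' not in model", objective_id), call. = FALSE)
  sm <- assemble_stoichiometric_matrix(model)
  n <- nrow(model$reactions)
  obj <- numeric(n); obj[sm$reaction_index[[objective_id]]] <- 1
  res <- solve_lp(obj, A_eq = as.matrix(sm$S), b_eq = numeric(nrow(sm$S)),
                  lb = model$reactions$lower_bound, ub = model$reactions$upper_bound,
                  maximize = direction == "max")
  flux_distribution(stats::setNames(res$v, model$reactions$id), objective_id,
                    res$value, res$status)
}

flux_distribution <- function(fluxes, objective_id, objective_value, status) {
  structure(list(fluxes = fluxes, objective_id = objective_id,
                 objective_value = objective_value, status = status),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("<flux_distribution> %s: objective %s = %s\n", x$status,
              x$objective_id,
              if (is.na(x$objective_value)) "NA" else format(x$objective_value, digits = 6)))
  invisible(x)
}

#' Parsimonious reference flux distribution
#'
#' FBA optima are generally non-unique; downstream analyses that consume the
#' whole flux vector (notably the MOMA reference) need a reproducible one.
#' This two-step LP first maximizes the objective, then - holding the
#' objective at at least `optimum_fraction` of that optimum - minimizes the
#' total absolute flux `sum(|v_i|)` via the standard positive/negative flux
#' splitting, which suppresses futile cycles and arbitrary parallel-path
#' splits.
#'
#' @param model A `metabolic_model`.
#' @param objective_id Objective reaction id (default: biomass).
#' @param optimum_fraction Fraction of the FBA optimum to retain
#'   (default 0.9999).
#' @return A `flux_distribution` (objective value re-read from the
#'   parsimonious vector) with attribute `total_flux` = `sum(|v|)`.
#' @export
parsimonious_reference <- function(model, objective_id = model$biomass_reaction_id,
                                   optimum_fraction = 0.9999) {
  fba <- solve_fba(model, objective_id)
  if (fba$status != "optimal") return(fba)
  sm <- assemble_stoichiometric_matrix(model)
  S <- as.matrix(sm$S)
  n <- ncol(S); m <- nrow(S)
  lb <- model$reactions$lower_bound; ub <- model$reactions$upper_bound
  # variables [p; q], v = p - q, p,q >= 0
  p_ub <- pmax(ub, 0); q_ub <- pmax(-lb, 0)
  A_eq <- cbind(S, -S)
  obj <- rep(1, 2 * n)
  A_ub <- NULL; b_ub <- NULL
  # bounds not captured by the split caps: lb > 0 forces v >= lb, ub < 0 forces v <= ub
  j_obj <- sm$reaction_index[[objective_id]]
  target <- fba$objective_value - abs(fba$objective_value) * (1 - optimum_fraction) - 1e-9
  rows <- list(); rhs <- numeric(0)
  for (j in seq_len(n)) {
    if (lb[j] > 0) { r <- numeric(2 * n); r[j] <- -1; r[n + j] <- 1
      rows <- c(rows, list(r)); rhs <- c(rhs, -lb[j]) }   # -(p-q) <= -lb
    if (ub[j] < 0) { r <- numeric(2 * n); r[j] <- 1; r[n + j] <- -1
      rows <- c(rows, list(r)); rhs <- c(rhs, ub[j]) }    # p-q <= ub
  }
  r <- numeric(2 * n); r[j_obj] <- -1; r[n + j_obj] <- 1
  rows <- c(rows, list(r)); rhs <- c(rhs, -target)        # v_obj >= target
  A_ub <- do.call(rbind, rows); b_ub <- rhs
  res <- solve_lp(obj, A_eq = A_eq, b_eq = numeric(m),
                  lb = rep(0, 2 * n), ub = c(p_ub, q_ub),
                  A_ub = A_ub, b_ub = b_ub, maximize = FALSE)
  if (res$status != "optimal") return(fba)  # fall back to the plain FBA vertex
  v <- res$v[seq_len(n)] - res$v[n + seq_len(n)]
  v[abs(v) < 1e-10] <- 0
  out <- flux_distribution(stats::setNames(v, model$reactions$id), objective_id,
                           v[j_obj], "optimal")
  attr(out, "total_flux") <- sum(abs(v))
  out
}
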