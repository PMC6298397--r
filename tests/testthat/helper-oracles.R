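# Independent oracles used across the suite.

# Brute-force LP optimum by basic-solution (vertex) enumeration over
# {v : S v = 0, lb <= v <= ub}. Every vertex of the box-constrained
# polytope has at least n - rank(S) variables pinned at a bound: enumerate
# all choices of pinned set and bound pattern, solve for the remaining
# variables, keep feasible points, and take the best objective. Exact up
# to linear-solve round-off; only usable at toy sizes.
enumerate_lp_optimum <- function(obj, S, lb, ub, maximize = TRUE, tol = 1e-8) {
  S <- as.matrix(S)
  n <- ncol(S)
  r <- qr(S)$rank
  d <- n - r
  best <- if (maximize) -Inf else Inf
  best_v <- NULL
  consider <- function(v) {
    if (any(v < lb - tol) || any(v > ub + tol)) return()
    if (max(abs(S %*% v)) > tol) return()
    val <- sum(obj * v)
    if ((maximize && val > best) || (!maximize && val < best)) {
      best <<- val; best_v <<- v
    }
  }
  if (d == 0) {
    v <- rep(0, n)  # full column rank and S v = 0 forces v = 0
    consider(v)
  } else {
    pin_sets <- utils::combn(n, d)
    patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), d)))
    for (k in seq_len(ncol(pin_sets))) {
      N <- pin_sets[, k]
      B <- setdiff(seq_len(n), N)
      SB <- S[, B, drop = FALSE]
      qb <- qr(SB)
      if (qb$rank < length(B)) next
      for (p in seq_len(nrow(patterns))) {
        vN <- ifelse(patterns[p, ], ub[N], lb[N])
        rhs <- -S[, N, drop = FALSE] %*% vN
        vB <- tryCatch(qr.coef(qb, rhs), error = function(e) NULL)
        if (is.null(vB) || anyNA(vB)) next
        v <- numeric(n); v[N] <- vN; v[B] <- vB
        consider(v)
      }
    }
  }
  if (is.null(best_v)) return(list(value = NA_real_, status = "infeasible"))
  list(value = best, v = best_v, status = "optimal")
}

# FBA objective through the enumeration oracle.
oracle_fba_optimum <- function(model, objective_id = model$biomass_reaction_id) {
  sm <- assemble_stoichiometric_matrix(model)
  obj <- numeric(nrow(model$reactions))
  obj[sm$reaction_index[[objective_id]]] <- 1
  enumerate_lp_optimum(obj, as.matrix(sm$S), model$reactions$lower_bound,
                       model$reactions$upper_bound)
}

# Independent GPR evaluation: rewrite the rule as an R logical expression
# and eval() it with genes bound to their knockout state.
oracle_eval_gpr <- function(rule_string, genes, knocked_out) {
  expr <- gsub("\\bor\\b", "||", gsub("\\band\\b", "&&", tolower(rule_string)))
  env <- new.env(parent = baseenv())
  for (g in genes) assign(tolower(g), !(g %in% knocked_out), envir = env)
  isTRUE(eval(parse(text = expr), envir = env))
}

# Seeded random GPR over <= max_genes genes, for truth-table property tests.
random_gpr <- function(n_genes, depth = 2) {
  genes <- paste0("g", seq_len(n_genes))
  build <- function(d) {
    if (d == 0 || stats::runif(1) < 0.35) return(sample(genes, 1))
    op <- sample(c("and", "or"), 1)
    k <- sample(2:3, 1)
    parts <- vapply(seq_len(k), function(i) {
      s <- build(d - 1)
      if (grepl(" ", s)) paste0("(", s, ")") else s
    }, character(1))
    paste(parts, collapse = paste0(" ", op, " "))
  }
  list(rule = build(depth), genes = genes)
}

# Three-reaction linear chain: source [0,10] -> A -> B -> sink. Used for
# the hand-solved MOMA projection and simple FBA checks.
chain3_model <- function(source_ub = 10) {
  mets <- rbind(metabolite("A"), metabolite("B"))
  rxns <- list(
    reaction("R1", c(A = 1), lower_bound = 0, upper_bound = source_ub),
    reaction("R2", c(A = -1, B = 1)),
    reaction("R3", c(B = -1)))
  metabolic_model(mets, rxns, biomass_reaction_id = "R3")
}

# A minimal toy spec that stays at <= 10 reactions so the enumeration
# oracle applies (8 core reactions + up to 2 planted chain steps).
small_toy_spec <- function(seed) {
  toy_model_spec(n_carbon_sources = 1, include_eps_pathway = FALSE,
                 n_isozyme_pairs = 0, n_planted_essential = seed %% 3,
                 seed = seed)
}

expect_steady_state <- function(model, fluxes, tol = 1e-6) {
  sm <- assemble_stoichiometric_matrix(model)
  resid <- max(abs(as.matrix(sm$S) %*% fluxes[model$reactions$id]))
  expect_lt(resid, tol)
}
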