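# Internal LP layer.
#
# Canonicalizes   max/min  obj' v
#                 s.t.     A_eq v = b_eq,  A_ub v <= b_ub,  lb <= v <= ub
# by turning every inequality row into an equality with a bounded slack,
# then hands the problem to the bounded-variable simplex (simplex.R).
# All bounds must be finite, so unbounded problems cannot arise.
solve_lp <- function(obj, A_eq, b_eq, lb, ub, A_ub = NULL, b_ub = NULL,
                     maximize = TRUE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n, all(is.finite(lb)), all(is.finite(ub)))
  if (any(lb > ub))
    return(list(v = rep(NA_real_, n), value = NA_real_, status = "infeasible"))
  A <- as.matrix(A_eq); b <- as.numeric(b_eq)
  cost <- obj; lo <- lb; hi <- ub
  if (!is.null(A_ub)) {
    A_ub <- as.matrix(A_ub)
    k <- nrow(A_ub)
    # slack s = b_ub - A_ub v >= 0, bounded by the box-implied row range
    smax <- vapply(seq_len(k), function(i) {
      row <- A_ub[i, ]
      b_ub[i] - sum(pmin(row * lb, row * ub))
    }, numeric(1))
    A <- rbind(cbind(A, matrix(0, nrow(A), k)),
               cbind(A_ub, diag(k)))
    b <- c(b, b_ub)
    cost <- c(cost, rep(0, k))
    lo <- c(lo, rep(0, k))
    hi <- c(hi, pmax(smax, 0))
  }
  res <- simplex_bounded(cost, A, b, lo, hi, maximize = maximize)
  if (res$status != "optimal")
    return(list(v = rep(NA_real_, n), value = NA_real_, status = res$status))
  v <- res$v[seq_len(n)]
  list(v = v, value = sum(obj * v), status = "optimal")
}
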