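# Internal bounded-variable two-phase simplex.
#
# Solves    min/max  c' v
#           s.t.     A v = b,   l <= v <= u   (l, u finite)
# with Bland's smallest-index pivoting rule, which guarantees termination
# on degenerate problems. The basic solution is recomputed from a fresh
# factorization at every iteration, trading speed for numerical
# robustness; at the network sizes this package targets (tens to a few
# hundred variables) that cost is negligible. Rank-deficient equality
# systems are handled by the phase-1 artificial variables staying basic at
# zero.
#
# Returns list(v, value, status) with status "optimal" or "infeasible"
# ("unbounded" cannot arise under finite box bounds).
simplex_bounded <- function(obj, A, b, lower, upper, maximize = TRUE,
                            tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A); n0 <- ncol(A)
  stopifnot(length(obj) == n0, length(lower) == n0, length(upper) == n0,
            length(b) == m, all(is.finite(lower)), all(is.finite(upper)))
  if (any(lower > upper + tol))
    return(list(v = rep(NA_real_, n0), value = NA_real_, status = "infeasible"))
  cmin <- if (maximize) -obj else obj
  # start every structural variable at its bound of smaller magnitude
  x <- ifelse(abs(lower) <= abs(upper), lower, upper)
  r <- as.vector(b - A %*% x)
  # artificial columns sign(r_i) e_i, value |r_i| >= 0
  sgn <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, nrow = m))
  n <- n0 + m
  lo <- c(lower, rep(0, m))
  hi <- c(upper, rep(Inf, m))
  x <- c(x, abs(r))
  basis <- n0 + seq_len(m)
  at_upper <- ifelse(abs(lower) <= abs(upper), FALSE, TRUE)
  at_upper <- c(at_upper, rep(FALSE, m))

  run_phase <- function(cost, x, basis, at_upper) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) stop("simplex iteration limit reached", call. = FALSE)
      nonbasic <- setdiff(seq_len(n), basis)
      B <- Afull[, basis, drop = FALSE]
      xN <- x[nonbasic]
      rhs <- b - if (length(nonbasic)) Afull[, nonbasic, drop = FALSE] %*% xN else 0
      xB <- tryCatch(as.vector(solve(B, rhs)), error = function(e) NULL)
      if (is.null(xB)) stop("singular basis in simplex", call. = FALSE)
      x[basis] <- xB
      y <- as.vector(solve(t(B), cost[basis]))
      # entering variable (Bland): smallest index with an improving reduced cost
      enter <- 0L; dir <- 0
      for (j in nonbasic) {
        if (lo[j] >= hi[j]) next  # fixed variable
        dj <- cost[j] - sum(y * Afull[, j])
        if (!at_upper[j] && dj < -tol) { enter <- j; dir <- 1; break }
        if (at_upper[j] && dj > tol) { enter <- j; dir <- -1; break }
      }
      if (enter == 0L) {
        return(list(x = x, basis = basis, at_upper = at_upper,
                    value = sum(cost * x)))
      }
      w <- as.vector(solve(B, Afull[, enter]))      # xB changes by -dir * w * t
      step_own <- hi[enter] - lo[enter]             # bound-to-bound flip
      step <- step_own; leave_pos <- 0L
      for (i in seq_len(m)) {
        delta <- -dir * w[i]
        if (abs(delta) < 1e-11) next
        lim <- if (delta > 0) (hi[basis[i]] - x[basis[i]]) / delta
               else (lo[basis[i]] - x[basis[i]]) / delta
        if (!is.finite(lim)) next
        lim <- max(lim, 0)
        if (lim < step - 1e-12 ||
            (lim < step + 1e-12 && (leave_pos == 0L || basis[i] < basis[leave_pos]))) {
          step <- lim; leave_pos <- i
        }
      }
      if (!is.finite(step)) stop("unbounded direction under finite bounds", call. = FALSE)
      x[enter] <- x[enter] + dir * step
      x[basis] <- x[basis] - dir * w * step
      if (leave_pos == 0L) {
        at_upper[enter] <- !at_upper[enter]         # flip to the opposite bound
      } else {
        lv <- basis[leave_pos]
        at_upper[lv] <- -dir * w[leave_pos] > 0     # left at the bound it hit
        x[lv] <- if (at_upper[lv]) hi[lv] else lo[lv]
        basis[leave_pos] <- enter
      }
    }
  }

  scale <- 1 + max(abs(b), 1)
  p1 <- run_phase(c(rep(0, n0), rep(1, m)), x, basis, at_upper)
  if (p1$value > 1e-7 * scale)
    return(list(v = rep(NA_real_, n0), value = NA_real_, status = "infeasible"))
  hi[n0 + seq_len(m)] <- 0                          # lock artificials at zero
  p2 <- run_phase(c(cmin, rep(0, m)), p1$x, p1$basis, p1$at_upper)
  v <- p2$x[seq_len(n0)]
  v <- pmin(pmax(v, lower), upper)
  list(v = v, value = sum(obj * v), status = "optimal")
}
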