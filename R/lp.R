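#' Solve a bounded linear program with a deterministic dense simplex
#'
#' Solves \eqn{\min / \max \; c^\top v} subject to \eqn{A v = b} and
#' \eqn{lb \le v \le ub} using a two-phase tableau simplex with Bland's
#' anti-cycling rule. The pivoting order is fully deterministic, so repeated
#' calls with identical inputs return bitwise-identical solutions -- a
#' requirement for reproducible flux balance analysis. Intended for the dense,
#' small-to-moderate programs arising from curated metabolic networks; it is
#' not a sparse large-scale solver.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n) of equality constraints `A v = b`.
#' @param b right-hand side (length m).
#' @param lb,ub lower/upper variable bounds (length n). Infinite bounds are
#'   clamped to +/- 1e6, far beyond any realistic flux.
#' @param maximize logical; maximize instead of minimize.
#' @param tol numeric feasibility/pivot tolerance.
#' @return list with `status` ("optimal", "infeasible", or "unbounded"),
#'   `objval` (objective at the optimum, on the original scale), and `x`
#'   (solution vector, length n).
#' @keywords internal
simplex_lp <- function(obj, A, b, lb, ub, maximize = FALSE, tol = 1e-9) {
  A <- as.matrix(A)
  n <- length(obj)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(b) == m, length(lb) == n, length(ub) == n)
  BIG <- 1e6
  lb <- pmax(lb, -BIG)
  ub <- pmin(ub, BIG)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", objval = NA_real_, x = rep(NA_real_, n)))
  }
  u <- ub - lb
  b2 <- as.numeric(b - A %*% lb)
  cost <- if (maximize) -obj else obj

  # standard form: variables y = v - lb >= 0 plus one slack per upper bound
  Aext <- rbind(cbind(A, matrix(0, m, n)),
                cbind(diag(n), diag(n)))
  bext <- c(b2, u)
  M <- m + n
  N <- 2L * n
  neg <- bext < 0
  Aext[neg, ] <- -Aext[neg, , drop = FALSE]
  bext[neg] <- -bext[neg]

  # full tableau with artificial identity on the right
  Tb <- cbind(Aext, diag(M), bext)
  basis <- N + seq_len(M)
  ncols <- N + M

  pivot <- function(Tb, prow, pcol) {
    Tb[prow, ] <- Tb[prow, ] / Tb[prow, pcol]
    other <- setdiff(seq_len(nrow(Tb)), prow)
    Tb[other, ] <- Tb[other, ] - outer(Tb[other, pcol], Tb[prow, ])
    Tb
  }

  run_phase <- function(Tb, basis, cvec, allowed, tol, max_iter = 20000L) {
    repeat {
      max_iter <- max_iter - 1L
      if (max_iter < 0L) stop("simplex iteration limit reached")
      cB <- cvec[basis]
      red <- cvec[seq_len(ncols)] - as.numeric(crossprod(cB, Tb[, seq_len(ncols), drop = FALSE]))
      cand <- which(red < -tol & allowed)
      if (!length(cand)) {
        return(list(Tb = Tb, basis = basis, status = "optimal"))
      }
      enter <- cand[1L]  # Bland: smallest eligible index
      col <- Tb[, enter]
      rhs <- Tb[, ncols + 1L]
      ratio <- ifelse(col > tol, rhs / col, Inf)
      if (all(is.infinite(ratio))) {
        return(list(Tb = Tb, basis = basis, status = "unbounded"))
      }
      rmin <- min(ratio)
      rows <- which(ratio <= rmin + tol)
      leave <- rows[which.min(basis[rows])]  # Bland on the leaving variable
      Tb <- pivot(Tb, leave, enter)
      basis[leave] <- enter
    }
  }

  # phase 1: drive artificials to zero
  c1 <- c(rep(0, N), rep(1, M))
  ph1 <- run_phase(Tb, basis, c1, allowed = rep(TRUE, ncols), tol = tol)
  Tb <- ph1$Tb; basis <- ph1$basis
  w <- sum(c1[basis] * Tb[, ncols + 1L])
  if (ph1$status != "optimal" || w > 1e-7) {
    return(list(status = "infeasible", objval = NA_real_, x = rep(NA_real_, n)))
  }
  # pivot remaining (zero-valued) artificials out of the basis where possible
  for (i in seq_along(basis)) {
    if (basis[i] > N) {
      j <- which(abs(Tb[i, seq_len(N)]) > tol)
      if (length(j)) {
        Tb <- pivot(Tb, i, j[1L])
        basis[i] <- j[1L]
      }
    }
  }
  keep <- basis <= N
  if (!all(keep)) {  # redundant rows: artificial basic at zero with no pivot
    Tb <- Tb[keep, , drop = FALSE]
    basis <- basis[keep]
  }

  # phase 2: real costs, artificial columns locked out
  c2 <- c(cost, rep(0, n), rep(0, M))
  allowed <- c(rep(TRUE, N), rep(FALSE, M))
  ph2 <- run_phase(Tb, basis, c2, allowed = allowed, tol = tol)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", objval = NA_real_, x = rep(NA_real_, n)))
  }
  Tb <- ph2$Tb; basis <- ph2$basis
  y <- rep(0, N)
  y[basis] <- Tb[, ncol(Tb)]
  v <- y[seq_len(n)] + lb
  list(status = "optimal", objval = sum(obj * v), x = v)
}
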