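#' Solve a bounded-variable linear program
#'
#' Two-phase primal simplex for problems of the form
#' \deqn{\max / \min\; c^\top x \quad \mathrm{s.t.}\; A x = b,\; l \le x \le u,}
#' the canonical shape of flux balance analysis (\eqn{A} is the stoichiometric
#' matrix, \eqn{b = 0}, and the bounds carry the medium and thermodynamic
#' constraints). Variables may have infinite bounds. The solver returns the
#' primal solution together with the row duals (shadow prices) and the
#' reduced costs \eqn{d = c - A^\top y}, both in the orientation of the stated
#' objective, so that \eqn{d_j} is the marginal change of the objective per
#' unit relaxation of the bound at which variable \eqn{j} is binding.
#'
#' Written in-package because no linear-programming package is available in
#' the target library; sized for the dense, small-to-medium systems used here.
#'
#' @param obj numeric objective coefficients, length n.
#' @param A constraint matrix (m x n), dense or anything `as.matrix` accepts.
#' @param b right-hand side, length m.
#' @param lb,ub variable bounds, length n; `-Inf`/`Inf` allowed.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol pivot/feasibility tolerance.
#' @param max_iter iteration cap across both phases.
#'
#' @return A list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `objective`, `x` (length n), `duals` (length m), `reduced_costs`
#'   (length n) and `iterations`.
#' @keywords internal
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub)) stop("lp_solve: lower bound exceeds upper bound")

  cmin <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  # start structural variables at a finite bound (lower preferred)
  x <- ifelse(is.finite(lb), lb, ifelse(is.finite(ub), ub, 0))
  at_upper <- !is.finite(lb) & is.finite(ub)

  r <- b - drop(A %*% x)
  # artificial columns: sign(r_i) * e_i so artificial values start >= 0
  sgn <- ifelse(r >= 0, 1, -1)
  AA <- cbind(A, diag(sgn, nrow = m))
  nn <- n + m
  LB <- c(lb, rep(0, m))
  UB <- c(ub, rep(Inf, m))
  basis <- (n + 1L):nn
  # nonbasic bound status for structural vars; basic entries ignored
  atu <- c(at_upper, rep(FALSE, m))
  xx <- c(x, abs(r))

  recompute_xB <- function(basis, atu, xx) {
    xN <- xx
    nb <- setdiff(seq_len(nn), basis)
    xN[nb] <- ifelse(atu[nb], UB[nb], ifelse(is.finite(LB[nb]), LB[nb], 0))
    # free nonbasic vars sit at 0
    xN[nb][!is.finite(LB[nb]) & !is.finite(UB[nb])] <- 0
    rhs <- b - AA[, nb, drop = FALSE] %*% xN[nb]
    xN[basis] <- drop(solve(AA[, basis, drop = FALSE], rhs))
    xN
  }

  run_phase <- function(cc, basis, atu, xx, phase, iter0) {
    iter <- iter0
    degen <- 0L
    bland <- FALSE
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) stop("lp_solve: iteration limit reached")
      B <- AA[, basis, drop = FALSE]
      y <- drop(solve(t(B), cc[basis]))
      d <- cc - drop(crossprod(AA, y))
      nb <- setdiff(seq_len(nn), basis)
      if (phase == 2L) nb <- nb[UB[nb] > LB[nb]]  # fixed vars (artificials) cannot enter
      free_nb <- !is.finite(LB[nb]) & !is.finite(UB[nb])
      can_inc <- d[nb] < -tol & (!atu[nb] | free_nb)
      can_dec <- d[nb] > tol & (atu[nb] | free_nb)
      cand <- nb[can_inc | can_dec]
      if (!length(cand)) {
        return(list(status = "optimal", basis = basis, atu = atu, xx = xx,
                    y = y, d = d, iter = iter))
      }
      j <- if (bland) min(cand) else cand[which.max(abs(d[cand]))]
      # move in the improving direction (free vars can go either way)
      dir <- if (!is.finite(LB[j]) && !is.finite(UB[j])) {
        if (d[j] < 0) 1 else -1
      } else if (atu[j]) -1 else 1
      w <- drop(solve(B, AA[, j]))
      xB <- xx[basis]
      # how far can x_j move?
      step_self <- if (is.finite(UB[j]) && is.finite(LB[j])) UB[j] - LB[j] else Inf
      best <- step_self
      leave <- 0L          # 0 = bound flip
      leave_to_upper <- FALSE
      for (i in seq_len(m)) {
        wi <- dir * w[i]
        if (wi > tol) {           # basic var i decreases
          if (is.finite(LB[basis[i]])) {
            s <- (xB[i] - LB[basis[i]]) / wi
            if (s < best - tol ||
                (s < best + tol && leave > 0L && basis[i] < basis[leave])) {
              best <- s; leave <- i; leave_to_upper <- FALSE
            }
          }
        } else if (wi < -tol) {   # basic var i increases
          if (is.finite(UB[basis[i]])) {
            s <- (UB[basis[i]] - xB[i]) / (-wi)
            if (s < best - tol ||
                (s < best + tol && leave > 0L && basis[i] < basis[leave])) {
              best <- s; leave <- i; leave_to_upper <- TRUE
            }
          }
        }
      }
      if (!is.finite(best)) {
        return(list(status = "unbounded", basis = basis, atu = atu, xx = xx,
                    y = y, d = d, iter = iter))
      }
      best <- max(best, 0)
      if (best < tol) degen <- degen + 1L else degen <- 0L
      if (degen > 2L * nn) bland <- TRUE
      if (leave == 0L) {
        atu[j] <- !atu[j]   # bound flip, basis unchanged
      } else {
        lv <- basis[leave]
        basis[leave] <- j
        atu[lv] <- leave_to_upper
        atu[j] <- FALSE
      }
      xx <- recompute_xB(basis, atu, xx)
    }
  }

  xx <- recompute_xB(basis, atu, xx)

  # Phase 1: drive artificials to zero
  c1 <- c(rep(0, n), rep(1, m))
  p1 <- run_phase(c1, basis, atu, xx, phase = 1L, iter0 = 0L)
  if (p1$status != "optimal" || sum(p1$xx[(n + 1L):nn]) > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n), duals = rep(NA_real_, m),
                reduced_costs = rep(NA_real_, n), iterations = p1$iter))
  }

  # Phase 2: artificials pinned to zero
  UB[(n + 1L):nn] <- 0
  c2 <- c(cmin, rep(0, m))
  p2 <- run_phase(c2, p1$basis, p1$atu, p1$xx, phase = 2L, iter0 = p1$iter)
  x <- p2$xx[seq_len(n)]
  if (p2$status == "unbounded") {
    return(list(status = "unbounded", objective = if (maximize) Inf else -Inf,
                x = x, duals = rep(NA_real_, m),
                reduced_costs = rep(NA_real_, n), iterations = p2$iter))
  }
  sign_back <- if (maximize) -1 else 1
  list(status = "optimal",
       objective = sum(obj * x),
       x = x,
       duals = sign_back * p2$y,
       reduced_costs = sign_back * p2$d[seq_len(n)],
       iterations = p2$iter)
}
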