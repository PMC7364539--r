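# Dense bounded-variable two-phase simplex.
#
# Solves  max/min  c'x   s.t.  A x = b,  lb <= x <= ub.
# This is the single LP interface behind all flux-balance protocols; the
# problems it sees are small (tens to a few hundred variables), so a dense
# implementation with a fresh basis factorisation per iteration is both
# simple and numerically safe.  Anti-cycling: Dantzig pricing switches to
# Bland's rule after a burn-in proportional to the problem size.

LP_BIG <- 1e6  # stand-in for infinite bounds; hit at optimum => unbounded

#' Solve a bounded linear program
#'
#' @param obj Objective coefficient vector (length n).
#' @param A Constraint matrix (m x n) of equality constraints `A x = b`.
#' @param b Right-hand side (length m).
#' @param lb,ub Variable bounds; infinities allowed.
#' @param maximize Logical; maximise (default) or minimise.
#' @param tol Reduced-cost / pivot tolerance.
#' @param max_iter Iteration cap across both phases.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"maxiter"`), `objective` and primal solution `x`.
#' @keywords internal
solve_lp <- function(obj, A, b, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = 20000L) {
  n <- length(obj)
  stopifnot(ncol(A) == n, length(b) == nrow(A), length(lb) == n, length(ub) == n)
  m <- nrow(A)
  sense <- if (maximize) 1 else -1
  cc <- sense * as.numeric(obj)

  lb0 <- as.numeric(lb); ub0 <- as.numeric(ub)
  had_inf <- !is.finite(lb0) | !is.finite(ub0)
  lbc <- pmax(lb0, -LP_BIG); ubc <- pmin(ub0, LP_BIG)
  if (any(lbc > ubc)) return(list(status = "infeasible", objective = NA_real_, x = NULL))

  if (m == 0L) {  # no balance constraints: optimum at bounds
    x <- ifelse(cc > 0, ubc, lbc)
    return(lp_finish(x, cc, sense, had_inf, lbc, ubc, n))
  }

  # --- set up with m artificials ------------------------------------------
  x_nb <- ifelse(abs(lbc) <= abs(ubc), lbc, ubc)      # nonbasic start values
  at_ub <- x_nb == ubc & lbc != ubc
  r <- as.numeric(b) - as.vector(A %*% x_nb)
  art_sign <- ifelse(r >= 0, 1, -1)
  Af <- cbind(A, diag(art_sign, m))
  N <- n + m
  LB <- c(lbc, rep(0, m)); UB <- c(ubc, rep(LP_BIG, m))
  status_ub <- c(at_ub, rep(FALSE, m))                # nonbasic-at-ub flags
  basis <- (n + 1L):N
  is_basic <- rep(FALSE, N); is_basic[basis] <- TRUE

  run_phase <- function(cost, basis, is_basic, status_ub, iter_used) {
    bland_after <- 50L + 10L * N
    it <- 0L
    repeat {
      it <- it + 1L
      if (iter_used + it > max_iter)
        return(list(code = "maxiter", basis = basis, is_basic = is_basic,
                    status_ub = status_ub, iters = it))
      Bm <- Af[, basis, drop = FALSE]
      qr_B <- qr(Bm)
      if (qr_B$rank < m)
        stop("simplex basis became singular; model may contain redundant rows",
             call. = FALSE)
      xN <- ifelse(status_ub, UB, LB)
      xN[basis] <- 0
      xB <- qr.solve(qr_B, as.numeric(b) - as.vector(Af %*% xN))
      y <- qr.solve(qr(t(Bm)), cost[basis])
      d <- cost - as.vector(crossprod(Af, y))
      d[basis] <- 0
      elig <- which(!is_basic & ((!status_ub & d > tol & LB != UB) |
                                   (status_ub & d < -tol & LB != UB)))
      if (!length(elig)) {
        x <- xN; x[basis] <- xB
        return(list(code = "optimal", x = x, basis = basis, is_basic = is_basic,
                    status_ub = status_ub, iters = it))
      }
      q <- if (it > bland_after) min(elig) else elig[which.max(abs(d[elig]))]
      dirn <- if (status_ub[q]) -1 else 1
      w <- qr.solve(qr_B, Af[, q])
      coef <- -w * dirn                               # d x_B / d t
      t_best <- UB[q] - LB[q]                         # entering flips bound
      leave <- 0L; leave_to_ub <- FALSE
      for (i in seq_len(m)) {
        if (coef[i] > tol) {
          ti <- (UB[basis[i]] - xB[i]) / coef[i]
          if (ti < t_best - tol) { t_best <- ti; leave <- i; leave_to_ub <- TRUE }
        } else if (coef[i] < -tol) {
          ti <- (LB[basis[i]] - xB[i]) / coef[i]
          if (ti < t_best - tol) { t_best <- ti; leave <- i; leave_to_ub <- FALSE }
        }
      }
      t_best <- max(t_best, 0)
      if (!is.finite(t_best))
        return(list(code = "unbounded", basis = basis, is_basic = is_basic,
                    status_ub = status_ub, iters = it))
      if (leave == 0L) {                              # bound flip, basis unchanged
        status_ub[q] <- !status_ub[q]
      } else {
        p <- basis[leave]
        is_basic[p] <- FALSE; is_basic[q] <- TRUE
        status_ub[p] <- leave_to_ub
        status_ub[q] <- FALSE
        basis[leave] <- q
      }
    }
  }

  # --- phase 1: drive artificials to zero ---------------------------------
  c1 <- c(rep(0, n), rep(-1, m))
  ph1 <- run_phase(c1, basis, is_basic, status_ub, 0L)
  if (ph1$code != "optimal")
    return(list(status = if (ph1$code == "maxiter") "maxiter" else "infeasible",
                objective = NA_real_, x = NULL))
  if (sum(ph1$x[(n + 1L):N]) > 1e-7)
    return(list(status = "infeasible", objective = NA_real_, x = NULL))

  # --- phase 2: artificials pinned at zero --------------------------------
  UB[(n + 1L):N] <- 0
  c2 <- c(cc, rep(0, m))
  ph2 <- run_phase(c2, ph1$basis, ph1$is_basic, ph1$status_ub, ph1$iters)
  if (ph2$code == "maxiter")
    return(list(status = "maxiter", objective = NA_real_, x = NULL))
  if (ph2$code == "unbounded")
    return(list(status = "unbounded", objective = NA_real_, x = NULL))
  lp_finish(ph2$x[seq_len(n)], cc, sense, had_inf, lbc, ubc, n)
}

lp_finish <- function(x, cc, sense, had_inf, lbc, ubc, n) {
  hit_big <- had_inf & (abs(x) >= LP_BIG * (1 - 1e-9))
  if (any(hit_big))
    return(list(status = "unbounded", objective = NA_real_, x = NULL))
  list(status = "optimal", objective = sense * sum(cc * x), x = x)
}
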