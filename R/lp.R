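#' Bounded-variable linear programming
#'
#' The package's LP backend: a dense two-phase primal simplex over variables
#' with (possibly infinite) lower/upper bounds, used by [solve_fba()],
#' [solve_pfba()] and the gap-filling search. Bland's smallest-index rule is
#' used for both entering and leaving choices, so the method terminates on the
#' degenerate problems metabolic steady-state constraints produce. Basic
#' values are re-solved from the basis factorization at every iteration,
#' which keeps accumulated error at the level of one dense solve.
#'
#' Solves: optimize `obj' x` subject to `A x (<=|=|>=) rhs`, `lb <= x <= ub`.
#'
#' @param obj numeric objective coefficients.
#' @param A constraint matrix (dense).
#' @param rhs right-hand sides.
#' @param sense character vector per row: `"<="`, `"="`, `">="`.
#' @param lb,ub bounds per variable (may be `-Inf`/`Inf`).
#' @param maximize logical.
#' @param tol feasibility/optimality tolerance.
#' @param max_iter iteration cap (default scales with problem size).
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objective`, `x` (primal solution, original variables only).
#' @keywords internal
#' @export
lp_solve <- function(obj, A, rhs, sense = rep("=", length(rhs)),
                     lb = rep(0, length(obj)), ub = rep(Inf, length(obj)),
                     maximize = FALSE, tol = 1e-9, max_iter = NULL) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(sense) == m,
            length(lb) == n, length(ub) == n, all(lb <= ub))

  # slacks turn inequalities into equalities
  n_slack <- sum(sense != "=")
  if (n_slack) {
    Sl <- matrix(0, m, n_slack)
    slb <- sub <- numeric(n_slack)
    k <- 0L
    for (i in seq_len(m)) {
      if (sense[[i]] == "=") next
      k <- k + 1L
      Sl[i, k] <- 1
      if (sense[[i]] == "<=") { slb[k] <- 0; sub[k] <- Inf }
      else { slb[k] <- -Inf; sub[k] <- 0 }
    }
    A <- cbind(A, Sl)
    lb <- c(lb, slb); ub <- c(ub, sub)
    obj2 <- c(obj, numeric(n_slack))
  } else obj2 <- obj

  res <- simplex_bounded(if (maximize) -obj2 else obj2, A, rhs, lb, ub,
                         tol = tol, max_iter = max_iter)
  if (res$status == "optimal") {
    x <- res$x[seq_len(n)]
    objective <- sum(obj * x)
    list(status = "optimal", objective = objective, x = x)
  } else {
    list(status = res$status, objective = NA_real_, x = rep(NA_real_, n))
  }
}

# Core phase-1/phase-2 simplex on: min c'x s.t. A x = b, lb <= x <= ub.
simplex_bounded <- function(cost, A, b, lb, ub, tol = 1e-9, max_iter = NULL) {
  m <- nrow(A); n <- ncol(A)
  if (is.null(max_iter)) max_iter <- 200L * (n + m) + 2000L

  # start every structural variable at a finite bound (0 for free variables)
  x <- ifelse(is.finite(lb), lb, ifelse(is.finite(ub), ub, 0))
  at_upper <- !is.finite(lb) & is.finite(ub)

  r <- b - as.numeric(A %*% x)
  sg <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sg, m))
  lb_f <- c(lb, rep(0, m))
  ub_f <- c(ub, rep(Inf, m))
  x_f <- c(x, abs(r))
  at_upper <- c(at_upper, rep(FALSE, m))
  basis <- n + seq_len(m)
  art <- n + seq_len(m)

  phase1_cost <- c(rep(0, n), rep(1, m))
  st <- simplex_iterate(phase1_cost, Afull, b, lb_f, ub_f, x_f, at_upper,
                        basis, tol, max_iter)
  if (st$status == "iteration-limit") return(list(status = "infeasible"))
  p1 <- sum(phase1_cost * st$x)
  if (p1 > 1e-7) return(list(status = "infeasible"))

  # pin artificials to zero and optimize the real objective
  ub_f[art] <- 0
  st$x[art] <- pmax(0, pmin(st$x[art], 0))
  phase2_cost <- c(cost, rep(0, m))
  st2 <- simplex_iterate(phase2_cost, Afull, b, lb_f, ub_f, st$x, st$at_upper,
                         st$basis, tol, max_iter)
  if (st2$status == "unbounded") return(list(status = "unbounded"))
  if (st2$status == "iteration-limit") {
    stop("simplex iteration limit reached; problem may be cycling", call. = FALSE)
  }
  list(status = "optimal", x = st2$x[seq_len(n)])
}

simplex_iterate <- function(cost, A, b, lb, ub, x, at_upper, basis, tol,
                            max_iter) {
  m <- nrow(A); n <- ncol(A)
  in_basis <- rep(FALSE, n); in_basis[basis] <- TRUE

  refresh_basics <- function(x, basis) {
    nonb <- which(!in_basis)
    rhs <- b - as.numeric(A[, nonb, drop = FALSE] %*% x[nonb])
    x[basis] <- solve(A[, basis, drop = FALSE], rhs)
    x
  }
  x <- refresh_basics(x, basis)

  for (iter in seq_len(max_iter)) {
    B <- A[, basis, drop = FALSE]
    y <- solve(t(B), cost[basis])
    nonb <- which(!in_basis)
    d <- cost[nonb] - as.numeric(t(A[, nonb, drop = FALSE]) %*% y)

    up <- at_upper[nonb]
    eligible <- (!up & d < -tol & x[nonb] < ub[nonb] - tol) |
                (up & d > tol & x[nonb] > lb[nonb] + tol)
    if (!any(eligible)) {
      return(list(status = "optimal", x = x, basis = basis, at_upper = at_upper))
    }
    j <- nonb[eligible][which.min(nonb[eligible])]  # Bland: smallest index
    dir <- if (at_upper[j]) -1 else 1               # x_j moves away from bound

    w <- as.numeric(solve(B, A[, j]))               # basic response: dx_B = -t*dir*w

    # ratio test: how far can x_j move before a basic variable, or x_j
    # itself, hits a bound
    cand_t <- numeric(0); cand_k <- integer(0); cand_to <- character(0)
    for (k in seq_len(m)) {
      wk <- dir * w[k]
      bi <- basis[k]
      if (wk > tol && is.finite(lb[bi])) {          # basic k decreases
        cand_t <- c(cand_t, max(0, (x[bi] - lb[bi]) / wk))
        cand_k <- c(cand_k, k); cand_to <- c(cand_to, "lb")
      } else if (wk < -tol && is.finite(ub[bi])) {  # basic k increases
        cand_t <- c(cand_t, max(0, (ub[bi] - x[bi]) / (-wk)))
        cand_k <- c(cand_k, k); cand_to <- c(cand_to, "ub")
      }
    }
    t_bound <- if (is.finite(ub[j]) && is.finite(lb[j])) ub[j] - lb[j] else Inf
    t_basic <- if (length(cand_t)) min(cand_t) else Inf
    if (!is.finite(min(t_basic, t_bound))) {
      return(list(status = "unbounded", x = x, basis = basis, at_upper = at_upper))
    }
    if (t_bound <= t_basic) {
      t_max <- t_bound; leave <- 0L; leave_to <- NA_character_
    } else {
      t_max <- t_basic
      tie <- which(cand_t <= t_basic + tol)
      pick <- tie[which.min(basis[cand_k[tie]])]    # Bland: smallest var index
      leave <- cand_k[pick]; leave_to <- cand_to[pick]
    }

    # apply step
    x[j] <- x[j] + dir * t_max
    x[basis] <- x[basis] - t_max * dir * w

    if (leave == 0L) {
      # bound flip: j stays nonbasic at its other bound
      at_upper[j] <- !at_upper[j]
    } else {
      out <- basis[leave]
      at_upper[out] <- identical(leave_to, "ub")
      x[out] <- if (at_upper[out]) ub[out] else lb[out]
      in_basis[out] <- FALSE
      in_basis[j] <- TRUE
      basis[leave] <- j
      x <- refresh_basics(x, basis)
    }
  }
  list(status = "iteration-limit", x = x, basis = basis, at_upper = at_upper)
}
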