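# Dense bounded-variable two-phase simplex.
#
# Solves   max/min  c'x
#          s.t.     Aeq x  = beq
#                   Aub x <= bub      (optional)
#                   lb <= x <= ub
#
# Written for the problem sizes this package works at (networks of tens to a
# few hundred reactions): the basis inverse is refactorised from scratch at
# every iteration, trading speed for numerical robustness, and Bland's rule
# kicks in after a run of degenerate steps so the method always terminates.

LP_TOL_FEAS <- 1e-9   # feasibility / artificial-elimination tolerance
LP_TOL_COST <- 1e-9   # reduced-cost optimality tolerance
LP_TOL_PIV <- 1e-10   # smallest pivot magnitude admitted in the ratio test

#' Solve a bounded linear program
#'
#' Internal workhorse behind [solve_fba()] and the gap-filling search.
#'
#' @param obj objective coefficient vector.
#' @param Aeq,beq equality constraint matrix and right-hand side.
#' @param lb,ub variable bounds (may contain `-Inf`/`Inf`).
#' @param sense `"max"` or `"min"`.
#' @param Aub,bub optional inequality rows `Aub x <= bub`.
#' @param maxit iteration cap.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (primal solution over the original variables) and `obj`.
#' @keywords internal
#' @noRd
lp_solve <- function(obj, Aeq, beq, lb, ub, sense = c("max", "min"),
                     Aub = NULL, bub = NULL, maxit = 20000L) {
  sense <- match.arg(sense)
  n0 <- length(obj)
  Aeq <- matrix(as.numeric(Aeq), nrow = length(beq), ncol = n0)
  stopifnot(length(lb) == n0, length(ub) == n0)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = rep(NA_real_, n0), obj = NA_real_))
  }

  A <- Aeq
  b <- as.numeric(beq)
  cvec <- as.numeric(obj)
  l <- as.numeric(lb)
  u <- as.numeric(ub)

  if (!is.null(Aub) && nrow(Aub) > 0) {
    Aub <- matrix(as.numeric(Aub), nrow = length(bub), ncol = n0)
    ns <- nrow(Aub)
    A <- rbind(cbind(A, matrix(0, nrow(A), ns)),
               cbind(Aub, diag(ns)))
    b <- c(b, as.numeric(bub))
    cvec <- c(cvec, rep(0, ns))
    l <- c(l, rep(0, ns))
    u <- c(u, rep(Inf, ns))
  }

  res <- simplex_bounded(cvec, A, b, l, u, maximize = (sense == "max"),
                         maxit = maxit)
  if (res$status == "optimal") {
    res$x <- res$x[seq_len(n0)]
    res$obj <- sum(obj * res$x)
  } else {
    res$x <- rep(NA_real_, n0)
    res$obj <- NA_real_
  }
  res
}

# status codes for nonbasic variables
NB_LOWER <- 1L
NB_UPPER <- 2L
NB_FREE <- 3L

simplex_bounded <- function(cvec, A, b, l, u, maximize = TRUE,
                            maxit = 20000L) {
  m <- nrow(A)
  n <- ncol(A)
  if (!maximize) cvec <- -cvec

  # initial nonbasic point: finite bound nearest zero, free variables at 0
  nb_status <- integer(n)
  x0 <- numeric(n)
  for (j in seq_len(n)) {
    if (is.finite(l[j])) {
      nb_status[j] <- NB_LOWER; x0[j] <- l[j]
    } else if (is.finite(u[j])) {
      nb_status[j] <- NB_UPPER; x0[j] <- u[j]
    } else {
      nb_status[j] <- NB_FREE; x0[j] <- 0
    }
  }

  # artificial columns forming the phase-1 basis
  r <- b - as.vector(A %*% x0)
  art_sign <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(art_sign, nrow = m))
  art_idx <- n + seq_len(m)
  lfull <- c(l, rep(0, m))
  ufull <- c(u, rep(Inf, m))

  basis <- art_idx
  status <- c(nb_status, rep(NB_LOWER, m))  # overwritten for basic vars

  phase1_c <- c(rep(0, n), rep(-1, m))  # maximize -sum(artificials)

  run <- simplex_core(phase1_c, Afull, b, lfull, ufull, basis, status,
                      enterable = rep(TRUE, n + m), maxit = maxit)
  if (run$status != "optimal") {
    stop("internal LP error: phase 1 did not terminate (", run$status, ")")
  }
  if (run$obj < -LP_TOL_FEAS * max(1, max(abs(b)))) {
    return(list(status = "infeasible"))
  }

  # freeze artificials at zero for phase 2
  lfull[art_idx] <- 0
  ufull[art_idx] <- 0
  enterable <- c(rep(TRUE, n), rep(FALSE, m))
  phase2_c <- c(cvec, rep(0, m))

  run2 <- simplex_core(phase2_c, Afull, b, lfull, ufull, run$basis,
                       run$nb_status, enterable = enterable, maxit = maxit)
  if (run2$status == "unbounded") {
    return(list(status = "unbounded"))
  }
  if (run2$status != "optimal") {
    stop("internal LP error: phase 2 did not terminate (", run2$status, ")")
  }
  x <- run2$x[seq_len(n)]
  list(status = "optimal", x = x,
       obj = if (maximize) sum(cvec * x) else -sum(cvec * x))
}

simplex_core <- function(cvec, A, b, l, u, basis, nb_status, enterable,
                         maxit = 20000L) {
  m <- nrow(A)
  n <- ncol(A)
  degen_run <- 0L

  for (it in seq_len(maxit)) {
    nonbasic <- setdiff(seq_len(n), basis)
    xN <- numeric(length(nonbasic))
    for (k in seq_along(nonbasic)) {
      j <- nonbasic[k]
      xN[k] <- switch(nb_status[j], l[j], u[j], 0)
    }
    B <- A[, basis, drop = FALSE]
    Binv <- tryCatch(solve(B), error = function(e) NULL)
    if (is.null(Binv)) stop("internal LP error: singular basis")
    rhs <- b - as.vector(A[, nonbasic, drop = FALSE] %*% xN)
    xB <- as.vector(Binv %*% rhs)

    y <- as.vector(t(cvec[basis]) %*% Binv)
    dN <- cvec[nonbasic] - as.vector(y %*% A[, nonbasic, drop = FALSE])

    # eligible entering variables (maximization)
    fixed <- (u[nonbasic] - l[nonbasic]) < 1e-14 & nb_status[nonbasic] != NB_FREE
    elig <- enterable[nonbasic] & !fixed & (
      (nb_status[nonbasic] == NB_LOWER & dN > LP_TOL_COST) |
      (nb_status[nonbasic] == NB_UPPER & dN < -LP_TOL_COST) |
      (nb_status[nonbasic] == NB_FREE & abs(dN) > LP_TOL_COST))

    if (!any(elig)) {
      x <- numeric(n)
      x[basis] <- xB
      x[nonbasic] <- xN
      return(list(status = "optimal", x = x, obj = sum(cvec * x),
                  basis = basis, nb_status = nb_status))
    }

    cand <- which(elig)
    if (degen_run > 2L * (m + n)) {
      pick <- cand[which.min(nonbasic[cand])]  # Bland
    } else {
      pick <- cand[which.max(abs(dN[cand]))]   # Dantzig
    }
    jent <- nonbasic[pick]
    dir <- if (nb_status[jent] == NB_UPPER) -1 else if (nb_status[jent] == NB_FREE) sign(dN[pick]) else 1

    w <- as.vector(Binv %*% A[, jent])

    # ratio test: how far can the entering variable move?
    ti <- rep(Inf, m)
    bound_hit <- integer(m)
    for (i in seq_len(m)) {
      wi <- dir * w[i]
      if (wi > LP_TOL_PIV && is.finite(l[basis[i]])) {        # basic decreases
        ti[i] <- max((xB[i] - l[basis[i]]) / wi, 0)
        bound_hit[i] <- NB_LOWER
      } else if (wi < -LP_TOL_PIV && is.finite(u[basis[i]])) { # basic increases
        ti[i] <- max((u[basis[i]] - xB[i]) / (-wi), 0)
        bound_hit[i] <- NB_UPPER
      }
    }
    tmax_basic <- min(ti)
    span <- if (nb_status[jent] == NB_FREE) Inf else u[jent] - l[jent]

    if (!is.finite(tmax_basic) && !is.finite(span)) {
      return(list(status = "unbounded"))
    }

    step <- min(tmax_basic, span)
    degen_run <- if (step < 1e-11) degen_run + 1L else 0L

    if (span <= tmax_basic) {
      # bound flip: the entering variable traverses to its other bound
      nb_status[jent] <- if (nb_status[jent] == NB_LOWER) NB_UPPER else NB_LOWER
    } else {
      ties <- which(ti <= tmax_basic + 1e-12)
      leave_pos <- if (degen_run > 2L * (m + n)) {
        ties[which.min(basis[ties])]            # Bland: smallest index
      } else {
        ties[which.max(abs(w[ties]))]           # largest pivot for stability
      }
      jleave <- basis[leave_pos]
      basis[leave_pos] <- jent
      nb_status[jleave] <- bound_hit[leave_pos]
    }
  }
  list(status = "maxit")
}
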