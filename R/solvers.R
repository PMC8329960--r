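# Internal linear and quadratic programming layer.
#
# All inner problems of the screening pipeline reduce to two primitives over
# the split (non-negative) flux space:
#   * an LP  max/min c'x  s.t.  Aeq x = beq, Aineq x <= bineq, lb <= x <= ub
#   * a QP   min x'Wx     s.t.  same constraint classes
# The LP rides on boot::simplex, the QP on quadprog::solve.QP. Stoichiometric
# equality systems are routinely rank-deficient, which boot::simplex cannot
# digest, so equalities are first reduced to a row basis by QR.

#' @keywords internal
#' @noRd
reduce_equalities <- function(Aeq, beq, tol = 1e-10) {
  if (is.null(Aeq) || nrow(Aeq) == 0L) {
    return(list(A = Aeq, b = beq))
  }
  dec <- qr(t(Aeq), tol = tol)
  keep <- dec$pivot[seq_len(dec$rank)]
  dropped <- setdiff(seq_len(nrow(Aeq)), keep)
  if (length(dropped) > 0L) {
    # consistency of the dropped rows: residual of b against the kept basis
    fit <- tryCatch(
      qr.solve(t(Aeq[keep, , drop = FALSE]) %*% Aeq[keep, , drop = FALSE] +
                 diag(1e-12, ncol(Aeq)),
               t(Aeq[keep, , drop = FALSE]) %*% beq[keep]),
      error = function(e) NULL)
    if (!is.null(fit)) {
      resid <- Aeq[dropped, , drop = FALSE] %*% fit - beq[dropped]
      if (any(abs(resid) > 1e-6)) {
        stop("equality system is inconsistent (redundant rows disagree)")
      }
    }
  }
  list(A = Aeq[keep, , drop = FALSE], b = beq[keep])
}

#' Solve a bounded linear program
#'
#' Thin, validated interface used by all flux computations. Maximizes or
#' minimizes `obj' x` subject to equality rows, optional `<=` rows, and box
#' bounds. Variables are shifted so the solver sees a non-negative problem.
#'
#' @param obj numeric objective vector.
#' @param Aeq,beq equality constraints `Aeq x = beq` (may be `NULL`).
#' @param Aineq,bineq inequality constraints `Aineq x <= bineq` (may be `NULL`).
#' @param lb,ub finite box bounds, `lb <= ub` componentwise.
#' @param maximize logical; maximize instead of minimize.
#' @return list with `x`, `value`, `status` (`"optimal"`, `"infeasible"` or
#'   `"unsolved"`).
#' @keywords internal
#' @noRd
lp_solve <- function(obj, Aeq = NULL, beq = NULL, Aineq = NULL, bineq = NULL,
                     lb, ub, maximize = FALSE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    return(list(x = NULL, value = NA_real_, status = "infeasible"))
  }
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("lp_solve requires finite bounds")
  }
  # shift x = y + lb so that y >= 0
  span <- ub - lb
  fixed <- span <= 1e-12
  if (all(fixed)) {
    x <- lb
    feas <- TRUE
    if (!is.null(Aeq) && nrow(Aeq) > 0L) {
      feas <- feas && all(abs(Aeq %*% x - beq) <= 1e-7)
    }
    if (!is.null(Aineq) && nrow(Aineq) > 0L) {
      feas <- feas && all(Aineq %*% x <= bineq + 1e-7)
    }
    if (!feas) return(list(x = NULL, value = NA_real_, status = "infeasible"))
    return(list(x = x, value = sum(obj * x), status = "optimal"))
  }

  if (!is.null(Aeq) && nrow(Aeq) > 0L) {
    beq_shift <- beq - as.vector(Aeq %*% lb)
    red <- reduce_equalities(Aeq, beq_shift)
    A3 <- red$A
    b3 <- red$b
    neg <- b3 < 0
    A3[neg, ] <- -A3[neg, , drop = FALSE]
    b3[neg] <- -b3[neg]
  } else {
    A3 <- NULL
    b3 <- NULL
  }
  # upper bounds as <= rows (identity rows restricted to non-fixed vars)
  idx_free <- which(!fixed)
  A1 <- matrix(0, length(idx_free), n)
  A1[cbind(seq_along(idx_free), idx_free)] <- 1
  b1 <- span[idx_free]
  if (!is.null(Aineq) && nrow(Aineq) > 0L) {
    bi_shift <- bineq - as.vector(Aineq %*% lb)
    flip <- bi_shift < 0
    A2 <- -Aineq[flip, , drop = FALSE]
    b2 <- -bi_shift[flip]
    A1 <- rbind(A1, Aineq[!flip, , drop = FALSE])
    b1 <- c(b1, bi_shift[!flip])
  } else {
    A2 <- NULL
    b2 <- NULL
  }
  # fixed variables are pinned by an equality row y_i = 0
  if (any(fixed)) {
    pin <- matrix(0, sum(fixed), n)
    pin[cbind(seq_len(sum(fixed)), which(fixed))] <- 1
    A3 <- rbind(A3, pin)
    b3 <- c(b3, rep(0, sum(fixed)))
  }

  res <- tryCatch(
    boot::simplex(a = obj,
                  A1 = A1, b1 = b1,
                  A2 = if (!is.null(A2) && nrow(A2) > 0L) A2 else NULL,
                  b2 = if (!is.null(A2) && nrow(A2) > 0L) b2 else NULL,
                  A3 = A3, b3 = b3,
                  maxi = maximize, n.iter = 50 * (n + 20), eps = 1e-10),
    error = function(e) NULL)
  if (is.null(res)) {
    return(list(x = NULL, value = NA_real_, status = "unsolved"))
  }
  if (res$solved != 1L) {
    status <- if (res$solved == 0L) "unsolved" else "infeasible"
    return(list(x = NULL, value = NA_real_, status = status))
  }
  x <- as.vector(res$soln) + lb
  list(x = x, value = sum(obj * x), status = "optimal")
}

#' Solve a convex minimum-norm quadratic program
#'
#' Minimizes `sum(w_i x_i^2)` subject to equalities, optional `>=` rows and
#' box bounds, via the dual active-set method of `quadprog`. Weights below a
#' small ridge are lifted to keep the Hessian positive definite.
#'
#' @param w non-negative per-variable quadratic weights.
#' @param Aeq,beq equality constraints.
#' @param Ageq,bgeq inequality constraints `Ageq x >= bgeq` (may be `NULL`).
#' @param lb,ub finite box bounds.
#' @param ridge weight floor keeping the problem strictly convex.
#' @keywords internal
#' @noRd
qp_min_norm <- function(w, Aeq = NULL, beq = NULL, Ageq = NULL, bgeq = NULL,
                        lb, ub, ridge = 1e-8) {
  n <- length(w)
  Dvec <- pmax(w, ridge) * 2
  red <- if (!is.null(Aeq) && nrow(Aeq) > 0L) {
    reduce_equalities(Aeq, beq)
  } else {
    list(A = NULL, b = NULL)
  }
  meq <- if (is.null(red$A)) 0L else nrow(red$A)
  Amat <- red$A
  bvec <- red$b
  if (!is.null(Ageq) && nrow(Ageq) > 0L) {
    Amat <- rbind(Amat, Ageq)
    bvec <- c(bvec, bgeq)
  }
  act <- !(ub - lb <= 1e-12 & abs(lb) < 1e-12)  # skip trivial 0-0 bounds rows
  ident <- diag(n)
  Amat <- rbind(Amat, ident[act, , drop = FALSE], -ident[act, , drop = FALSE])
  bvec <- c(bvec, lb[act], -ub[act])
  if (any(!act)) {
    # pinned variables become equalities up front
    pin <- ident[!act, , drop = FALSE]
    Amat <- rbind(pin, Amat)
    bvec <- c(lb[!act], bvec)
    meq <- meq + sum(!act)
  }
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = diag(Dvec, n), dvec = rep(0, n),
                       Amat = t(Amat), bvec = bvec, meq = meq),
    error = function(e) e)
  if (inherits(sol, "error")) {
    return(list(x = NULL, value = NA_real_, status = "infeasible",
                message = conditionMessage(sol)))
  }
  x <- pmin(pmax(sol$solution, lb), ub)
  list(x = x, value = sum(pmax(w, 0) * x^2), status = "optimal")
}
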