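#' Generic linear-programming interface
#'
#' The optimization stack (FBA, pFBA, FVA) is written against a small generic
#' LP description so that the metabolic model stays a pure `S v = 0` system
#' and the solver backend can be swapped. Two dense-simplex backends are
#' provided: `"simplex"` (via [boot::simplex()]) and `"dense"` (via
#' [pracma::linprog()], with variable bounds encoded as explicit inequality
#' rows). The two backends use different tableau formulations, so agreement
#' between them is a meaningful cross-check and is exercised in the test
#' suite.
#'
#' @param objective numeric vector of objective coefficients (minimized).
#' @param A constraint matrix (dense), one row per constraint.
#' @param sense character vector, one of `"="`, `"<="`, `">="` per row.
#' @param rhs numeric right-hand side, one per row.
#' @param lb,ub numeric variable bounds; must be finite (the package encodes
#'   "unconstrained" as +/- 1000 following the COBRA convention).
#' @param vars optional character vector of variable names.
#'
#' @return an object of class `lp_problem`.
#' @seealso [solve_lp()]
#' @export
lp_problem <- function(objective, A, sense, rhs, lb, ub, vars = NULL) {
  A <- as.matrix(A)
  n <- length(objective)
  stopifnot(ncol(A) == n, nrow(A) == length(sense), length(sense) == length(rhs),
            length(lb) == n, length(ub) == n)
  if (!all(sense %in% c("=", "<=", ">=")))
    stop("constraint sense must be one of '=', '<=', '>='")
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("variable bounds must be finite; encode unconstrained as +/- 1000")
  if (any(lb > ub + 1e-12))
    stop("infeasible bound pair: lower bound exceeds upper bound")
  if (is.null(vars)) vars <- paste0("v", seq_len(n))
  structure(list(objective = as.numeric(objective), A = A,
                 sense = as.character(sense), rhs = as.numeric(rhs),
                 lb = as.numeric(lb), ub = as.numeric(ub), vars = vars),
            class = "lp_problem")
}

# Reduce an equality system to a row basis via QR of t(A). Stoichiometric
# matrices are routinely rank-deficient (conserved moieties, duplicated
# balances) and both dense backends fail on dependent equality rows. Dropped
# rows are re-verified at the solution by solve_lp().
reduce_equality_rows <- function(A, b, tol = 1e-10) {
  if (nrow(A) <= 1L) return(list(A = A, b = b))
  qrd <- qr(t(A), tol = tol)
  keep <- sort(qrd$pivot[seq_len(qrd$rank)])
  list(A = A[keep, , drop = FALSE], b = b[keep])
}

solve_lp_boot <- function(obj, Aeq, beq, Ale, ble, ub, maxiter, eps) {
  n <- length(obj)
  neg <- beq < 0
  Aeq[neg, ] <- -Aeq[neg, , drop = FALSE]
  beq[neg] <- -beq[neg]
  A1 <- rbind(diag(n), Ale)
  b1 <- c(ub, ble)
  # boot::simplex mishandles <= rows with negative rhs: flip them to >=
  negle <- b1 < 0
  A2 <- -A1[negle, , drop = FALSE]
  b2 <- -b1[negle]
  A1 <- A1[!negle, , drop = FALSE]
  b1 <- b1[!negle]
  res <- tryCatch(
    boot::simplex(a = obj, A1 = A1, b1 = b1,
                  A2 = if (nrow(A2)) A2 else NULL, b2 = if (nrow(A2)) b2 else NULL,
                  A3 = Aeq, b3 = beq, maxi = FALSE, n.iter = maxiter, eps = eps),
    error = function(e) e)
  if (inherits(res, "error"))
    return(list(status = "solver_error", x = NULL, message = conditionMessage(res)))
  if (res$solved == -1) return(list(status = "infeasible", x = NULL))
  if (res$solved == 0)  return(list(status = "maxiter", x = NULL))
  list(status = "optimal", x = as.numeric(res$soln)[seq_len(n)])
}

solve_lp_dense <- function(obj, Aeq, beq, Ale, ble, ub, maxiter) {
  n <- length(obj)
  A <- rbind(diag(n), Ale)
  b <- c(ub, ble)
  res <- tryCatch(
    pracma::linprog(cc = obj, A = A, b = b, Aeq = Aeq, beq = beq,
                    maxiter = maxiter),
    error = function(e) e)
  if (inherits(res, "error"))
    return(list(status = "solver_error", x = NULL, message = conditionMessage(res)))
  if (!identical(res$errno, 1L) && !isTRUE(res$errno == 1))
    return(list(status = "infeasible", x = NULL))
  list(status = "optimal", x = as.numeric(res$x)[seq_len(n)])
}

#' Solve a linear program
#'
#' Minimizes `objective' x` subject to the rows of `A` and the variable
#' bounds. Internally variables are shifted to `x - lb >= 0`, the equality
#' block is reduced to a row basis, and every original constraint is
#' re-verified at the returned point with tolerance `feas_tol`; a solution
#' violating a dropped (dependent but inconsistent) row is reported
#' infeasible.
#'
#' @param lp an [lp_problem()].
#' @param backend `"simplex"` ([boot::simplex()]) or `"dense"`
#'   ([pracma::linprog()] with bounds as inequality rows).
#' @param maxiter simplex iteration cap.
#' @param feas_tol feasibility tolerance used to verify the returned point.
#' @param eps pivoting tolerance passed to the `"simplex"` backend.
#'
#' @return list with elements `status` (`"optimal"`, `"infeasible"`,
#'   `"maxiter"` or `"solver_error"`), `x` (named solution vector when
#'   optimal) and `objective`.
#' @export
solve_lp <- function(lp, backend = c("simplex", "dense"), maxiter = 20000L,
                     feas_tol = 1e-6, eps = 1e-10) {
  stopifnot(inherits(lp, "lp_problem"))
  backend <- match.arg(backend)

  # presolve: substitute out variables fixed by their bounds (closed
  # exchanges, maintenance drains, ...). Both dense backends misbehave on
  # zero-width variables, and eliminating them shrinks the tableau.
  fixed <- lp$ub - lp$lb < 1e-12
  if (any(fixed)) {
    free <- !fixed
    contrib <- as.numeric(lp$A[, fixed, drop = FALSE] %*% lp$lb[fixed])
    sub <- lp_problem(lp$objective[free], lp$A[, free, drop = FALSE],
                      lp$sense, lp$rhs - contrib, lp$lb[free], lp$ub[free],
                      vars = lp$vars[free])
    if (!any(free)) {
      # fully determined system: just check feasibility of the fixed point
      v <- lp$lb
      names(v) <- lp$vars
      lhs <- as.numeric(lp$A %*% v)
      eqv <- lp$sense == "="; lev <- lp$sense == "<="; gev <- lp$sense == ">="
      ok <- max(c(0, abs(lhs[eqv] - lp$rhs[eqv]),
                  pmax(lhs[lev] - lp$rhs[lev], 0),
                  pmax(lp$rhs[gev] - lhs[gev], 0))) <= feas_tol
      return(if (ok) list(status = "optimal", x = v,
                          objective = sum(lp$objective * v))
             else list(status = "infeasible", x = NULL, objective = NA_real_))
    }
    res <- solve_lp(sub, backend = backend, maxiter = maxiter,
                    feas_tol = feas_tol, eps = eps)
    if (res$status != "optimal") return(res)
    v <- numeric(length(lp$objective))
    v[fixed] <- lp$lb[fixed]
    v[free] <- res$x
    names(v) <- lp$vars
    return(list(status = "optimal", x = v,
                objective = sum(lp$objective * v)))
  }
  n <- length(lp$objective)

  # shift x = v - lb so that x >= 0
  shift <- lp$lb
  rhs_shift <- as.numeric(lp$A %*% shift)
  ubx <- lp$ub - lp$lb

  eq <- lp$sense == "="
  Aeq <- lp$A[eq, , drop = FALSE]
  beq <- lp$rhs[eq] - rhs_shift[eq]
  # normalize <=/>= rows to <=
  le <- lp$sense == "<="
  ge <- lp$sense == ">="
  Ale <- rbind(lp$A[le, , drop = FALSE], -lp$A[ge, , drop = FALSE])
  ble <- c(lp$rhs[le] - rhs_shift[le], -(lp$rhs[ge] - rhs_shift[ge]))

  rr <- reduce_equality_rows(Aeq, beq)

  res <- switch(backend,
    simplex = solve_lp_boot(lp$objective, rr$A, rr$b, Ale, ble, ubx, maxiter, eps),
    dense   = solve_lp_dense(lp$objective, rr$A, rr$b, Ale, ble, ubx, maxiter))

  if (res$status != "optimal")
    return(list(status = res$status, x = NULL, objective = NA_real_,
                message = res$message))

  v <- res$x + shift
  names(v) <- lp$vars
  # verify all original rows (including any dropped dependent equalities)
  lhs <- as.numeric(lp$A %*% v)
  viol <- max(c(0, abs(lhs[eq] - lp$rhs[eq]),
                pmax(lhs[le] - lp$rhs[le], 0),
                pmax(lp$rhs[ge] - lhs[ge], 0),
                pmax(lp$lb - v, 0), pmax(v - lp$ub, 0)))
  if (viol > feas_tol)
    return(list(status = "infeasible", x = NULL, objective = NA_real_,
                message = sprintf("constraint residual %.3g at solver optimum", viol)))
  list(status = "optimal", x = v,
       objective = sum(lp$objective * v))
}
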