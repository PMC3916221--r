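# Linear and integer-linear programming. Problems here are tiny (reaction
# balancing: ~a dozen variables; toy flux models: tens of reactions), so a
# dense two-phase simplex (simplex.R) plus a plain branch-and-bound is
# entirely adequate.

#' Solve a bounded linear program
#'
#' Maximizes (or minimizes) `obj %*% x` subject to `A_eq x = b_eq`,
#' `A_le x <= b_le` and box bounds `lb <= x <= ub`. All bounds must be
#' finite; variables are shifted to the simplex standard form internally.
#'
#' @param obj objective coefficient vector.
#' @param lb,ub finite bound vectors.
#' @param A_eq,b_eq equality constraints (optional).
#' @param A_le,b_le inequality constraints (optional).
#' @param maximize logical.
#' @return list with `status` ("optimal" or "infeasible"), `objval` and
#'   `x`.
#' @export
lp_solve <- function(obj, lb, ub, A_eq = NULL, b_eq = NULL,
                     A_le = NULL, b_le = NULL, maximize = TRUE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("lp_solve requires finite variable bounds", call. = FALSE)
  }
  if (any(lb > ub + 1e-9)) {
    return(list(status = "infeasible", objval = NA_real_, x = NULL))
  }
  # shift w = x - lb, w >= 0; upper bounds become rows
  A <- diag(n)
  b <- ub - lb
  type <- rep("<=", n)
  add_rows <- function(M, rhs, tp) {
    if (is.null(M)) return(invisible())
    M <- matrix(M, ncol = n)
    rhs <- rhs - as.vector(M %*% lb)
    # row-equilibrate and normalize signs so every rhs is non-negative
    mx <- apply(abs(M), 1, max)
    zero <- mx == 0
    if (any(zero & abs(rhs) > 1e-12 & tp == "=") ||
        any(zero & rhs < -1e-12 & tp == "<=")) {
      return("infeasible")
    }
    M <- M[!zero, , drop = FALSE]
    rhs <- rhs[!zero] / mx[!zero]
    M <- M / mx[!zero]
    tpv <- rep(tp, nrow(M))
    neg <- rhs < 0
    M[neg, ] <- -M[neg, , drop = FALSE]
    rhs[neg] <- -rhs[neg]
    tpv[neg] <- ifelse(tpv[neg] == "<=", ">=",
                       ifelse(tpv[neg] == ">=", "<=", "="))
    A <<- rbind(A, M)
    b <<- c(b, rhs)
    type <<- c(type, tpv)
    invisible()
  }
  if (identical(add_rows(A_le, b_le, "<="), "infeasible") ||
      identical(add_rows(A_eq, b_eq, "="), "infeasible")) {
    return(list(status = "infeasible", objval = NA_real_, x = NULL))
  }
  res <- simplex_core(obj, A, b, type, maximize = maximize)
  if (res$status != "optimal") {
    return(list(status = res$status, objval = NA_real_, x = NULL))
  }
  x <- res$x + lb
  list(status = "optimal", objval = sum(obj * x), x = x)
}

#' Solve a small bounded integer linear program
#'
#' Branch-and-bound over [lp_solve()] relaxations. Every variable listed
#' in `int_idx` is forced integral; branching picks the most fractional
#' variable, and nodes are pruned against the incumbent.
#'
#' @inheritParams lp_solve
#' @param int_idx indices of integer-constrained variables (default all).
#' @param tol integrality tolerance.
#' @param incumbent optional feasible integral starting solution (a list
#'   with `objval`, `x`) used to prune the search.
#' @return list with `status` ("optimal" or "infeasible"), `objval`, `x`.
#' @export
milp_solve <- function(obj, lb, ub, A_eq = NULL, b_eq = NULL,
                       A_le = NULL, b_le = NULL, maximize = FALSE,
                       int_idx = seq_along(obj), tol = 1e-6,
                       incumbent = NULL) {
  best <- list(objval = if (maximize) -Inf else Inf, x = NULL)
  if (!is.null(incumbent)) best <- incumbent
  sense <- if (maximize) 1 else -1
  stack <- list(list(lb = lb, ub = ub))
  nodes <- 0L
  while (length(stack) > 0 && nodes < 50000L) {
    nodes <- nodes + 1L
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    rel <- lp_solve(obj, node$lb, node$ub, A_eq, b_eq, A_le, b_le, maximize)
    if (rel$status != "optimal") next
    if (sense * rel$objval <= sense * best$objval + tol) next # bound
    frac <- abs(rel$x[int_idx] - round(rel$x[int_idx]))
    if (all(frac <= tol)) {
      x <- rel$x
      x[int_idx] <- round(x[int_idx])
      best <- list(objval = sum(obj * x), x = x)
      next
    }
    i <- int_idx[which.max(frac)]
    v <- rel$x[i]
    lo <- node; lo$ub[i] <- floor(v)
    hi <- node; hi$lb[i] <- ceiling(v)
    stack[[length(stack) + 1L]] <- lo
    stack[[length(stack) + 1L]] <- hi
  }
  if (is.null(best$x)) {
    return(list(status = "infeasible", objval = NA_real_, x = NULL))
  }
  list(status = "optimal", objval = best$objval, x = best$x)
}
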