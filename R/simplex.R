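# Dense two-phase primal simplex with Bland's anti-cycling rule.
# Problems in this package are tiny (at most a few dozen variables and
# constraints), so the full-tableau method with a conservative pivot
# tolerance is both fast enough and — unlike lighter textbook
# implementations — reliable on degenerate flux and balancing systems.

# Solve: max/min a'x  s.t.  A x (type) b,  x >= 0, with b >= 0 required
# (callers normalize row signs). type is a character vector of "<=",
# ">=", "=". Returns list(status, x, objval).
simplex_core <- function(a, A, b, type, maximize = TRUE, tol = 1e-9) {
  m <- nrow(A)
  n <- ncol(A)
  if (!maximize) {
    res <- simplex_core(-a, A, b, type, TRUE, tol)
    if (res$status == "optimal") res$objval <- -res$objval
    return(res)
  }
  n_slack <- sum(type == "<=")
  n_surp <- sum(type == ">=")
  n_art <- sum(type != "<=")
  ncol_t <- n + n_slack + n_surp + n_art
  T <- matrix(0, m, ncol_t)
  T[, seq_len(n)] <- A
  basis <- integer(m)
  si <- n
  ai <- n + n_slack + n_surp
  for (i in seq_len(m)) {
    if (type[i] == "<=") {
      si <- si + 1L
      T[i, si] <- 1
      basis[i] <- si
    } else {
      if (type[i] == ">=") {
        si <- si + 1L
        T[i, si] <- -1
      }
      ai <- ai + 1L
      T[i, ai] <- 1
      basis[i] <- ai
    }
  }
  rhs <- b
  art_cols <- seq(n + n_slack + n_surp + 1L, length.out = n_art)

  run_phase <- function(obj_row) {
    # full-tableau iterations with Bland's rule; mutates T, rhs, basis
    repeat {
      # reduced costs: c_j - c_B' B^-1 A_j ; tableau is kept in
      # canonical form so reduced costs are obj_row adjusted by basis
      cb <- obj_row[basis]
      red <- obj_row - as.vector(cb %*% T)
      red[basis] <- 0
      enter <- which(red > tol)
      if (length(enter) == 0) {
        return("optimal")
      }
      j <- min(enter) # Bland: smallest index
      col <- T[, j]
      pos <- which(col > tol)
      if (length(pos) == 0) {
        return("unbounded")
      }
      ratio <- rhs[pos] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      i <- cand[which.min(basis[cand])] # Bland on the leaving variable
      # pivot on (i, j)
      piv <- T[i, j]
      T[i, ] <<- T[i, ] / piv
      rhs[i] <<- rhs[i] / piv
      for (r in seq_len(m)) {
        if (r != i && abs(T[r, j]) > 0) {
          rhs[r] <<- rhs[r] - T[r, j] * rhs[i]
          T[r, ] <<- T[r, ] - T[r, j] * T[i, ]
        }
      }
      basis[i] <<- j
    }
  }

  if (n_art > 0) {
    phase1 <- rep(0, ncol_t)
    phase1[art_cols] <- -1
    st <- run_phase(phase1)
    art_val <- sum(rhs[basis %in% art_cols])
    if (st != "optimal" || art_val > 1e-7) {
      return(list(status = "infeasible", x = NULL, objval = NA_real_))
    }
    # pivot remaining artificials out of the basis where possible
    for (i in which(basis %in% art_cols)) {
      j <- which(abs(T[i, seq_len(n + n_slack + n_surp)]) > tol)
      if (length(j) > 0) {
        jj <- j[1]
        piv <- T[i, jj]
        T[i, ] <- T[i, ] / piv
        rhs[i] <- rhs[i] / piv
        for (r in seq_len(m)) {
          if (r != i && abs(T[r, jj]) > 0) {
            rhs[r] <- rhs[r] - T[r, jj] * rhs[i]
            T[r, ] <- T[r, ] - T[r, jj] * T[i, ]
          }
        }
        basis[i] <- jj
      }
      # a row whose only support is artificial is redundant; leaving the
      # artificial basic at value zero is harmless
    }
    # forbid artificials from re-entering
    T[, art_cols] <- 0
  }
  phase2 <- rep(0, ncol_t)
  phase2[seq_len(n)] <- a
  st <- run_phase(phase2)
  if (st == "unbounded") {
    return(list(status = "unbounded", x = NULL, objval = NA_real_))
  }
  x <- numeric(n)
  keep <- basis <= n
  x[basis[keep]] <- rhs[keep]
  list(status = "optimal", x = x, objval = sum(a * x))
}
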