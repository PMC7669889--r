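## A small, exact two-phase dense simplex (Bland's rule, no cycling) used as
## the pure-R LP engine.  It is deliberately independent of the HiGHS back
## end so that oracle cross-checks and implementation never share a solver.
## Problem sizes here are tiny (tens of variables), where a dense tableau is
## perfectly adequate.

## minimize c'x s.t. A x (dir) b, x >= 0, with dir in {"<=", ">=", "="}.
## Returns list(status, x, objective).
.simplexCore <- function(cc, A, dir, b, tol = 1e-9, maxit = 10000L) {
  m <- nrow(A); n <- ncol(A)
  ## normalize to b >= 0
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  dir[flip] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[flip]]
  nSlack <- sum(dir == "<=")
  nSurp <- sum(dir == ">=")
  nArt <- sum(dir != "<=")
  N <- n + nSlack + nSurp + nArt
  T <- matrix(0, m, N)
  T[, seq_len(n)] <- A
  basis <- integer(m)
  js <- n; jr <- n + nSlack; ja <- n + nSlack + nSurp
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      js <- js + 1L; T[i, js] <- 1; basis[i] <- js
    } else if (dir[i] == ">=") {
      jr <- jr + 1L; T[i, jr] <- -1
      ja <- ja + 1L; T[i, ja] <- 1; basis[i] <- ja
    } else {
      ja <- ja + 1L; T[i, ja] <- 1; basis[i] <- ja
    }
  }
  artCols <- seq.int(n + nSlack + nSurp + 1L, length.out = nArt)
  runPhase <- function(T, b, basis, obj, allowed) {
    for (it in seq_len(maxit)) {
      ## reduced costs: obj - obj[basis] %*% T
      y <- obj[basis]
      red <- obj - as.numeric(y %*% T)
      red[!allowed] <- Inf
      ent <- which(red < -tol)
      if (!length(ent)) {
        return(list(T = T, b = b, basis = basis,
                    value = sum(obj[basis] * b), status = "optimal"))
      }
      j <- min(ent)  # Bland
      col <- T[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(status = "unbounded"))
      ratio <- b[pos] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      i <- cand[which.min(basis[cand])]  # Bland tie-break
      piv <- T[i, j]
      T[i, ] <- T[i, ] / piv; b[i] <- b[i] / piv
      for (k in seq_len(nrow(T))) {
        if (k != i && abs(T[k, j]) > tol) {
          b[k] <- b[k] - T[k, j] * b[i]
          T[k, ] <- T[k, ] - T[k, j] * T[i, ]
        }
      }
      basis[i] <- j
    }
    list(status = "maxit")
  }
  ## phase 1
  if (nArt > 0) {
    obj1 <- numeric(N); obj1[artCols] <- 1
    ## reduce rows so artificial basis is canonical (already identity)
    ph1 <- runPhase(T, b, basis, obj1, allowed = rep(TRUE, N))
    if (!identical(ph1$status, "optimal")) return(list(status = "error"))
    if (ph1$value > 1e-7) return(list(status = "infeasible"))
    T <- ph1$T; b <- ph1$b; basis <- ph1$basis
    ## drive remaining artificials out of the basis where possible
    for (i in which(basis %in% artCols)) {
      j <- which(abs(T[i, seq_len(n + nSlack + nSurp)]) > tol)[1]
      if (!is.na(j)) {
        piv <- T[i, j]
        T[i, ] <- T[i, ] / piv; b[i] <- b[i] / piv
        for (k in seq_len(nrow(T))) {
          if (k != i && abs(T[k, j]) > tol) {
            b[k] <- b[k] - T[k, j] * b[i]
            T[k, ] <- T[k, ] - T[k, j] * T[i, ]
          }
        }
        basis[i] <- j
      }
    }
  }
  ## phase 2
  obj2 <- c(cc, numeric(N - n))
  allowed <- rep(TRUE, N); allowed[artCols] <- FALSE
  ph2 <- runPhase(T, b, basis, obj2, allowed)
  if (identical(ph2$status, "unbounded")) return(list(status = "unbounded"))
  if (!identical(ph2$status, "optimal")) return(list(status = "error"))
  x <- numeric(N)
  x[ph2$basis] <- ph2$b
  list(status = "optimal", x = x[seq_len(n)], objective = sum(cc * x[seq_len(n)]))
}

## Solve a standard-form lpProblem with the pure-R simplex.
.solveSimplexR <- function(p) {
  if (any(p$integrality != 0L)) {
    stop("the simplex engine solves LPs only", call. = FALSE)
  }
  n <- length(p$obj)
  A <- as.matrix(p$A)
  rows <- list(); rhs <- c(); dir <- c()
  addRow <- function(a, b, d) {
    rows[[length(rows) + 1L]] <<- a; rhs[length(rhs) + 1L] <<- b
    dir[length(dir) + 1L] <<- d
  }
  for (k in seq_len(nrow(A))) {
    if (is.finite(p$clb[k]) && is.finite(p$cub[k]) && p$clb[k] == p$cub[k]) {
      addRow(A[k, ], p$cub[k], "=")
    } else {
      if (is.finite(p$cub[k])) addRow(A[k, ], p$cub[k], "<=")
      if (is.finite(p$clb[k])) addRow(A[k, ], p$clb[k], ">=")
    }
  }
  I <- diag(n)
  for (j in seq_len(n)) {
    if (is.finite(p$vlb[j]) && is.finite(p$vub[j]) && p$vlb[j] == p$vub[j]) {
      addRow(I[j, ], p$vub[j], "=")
    } else {
      if (is.finite(p$vub[j])) addRow(I[j, ], p$vub[j], "<=")
      if (is.finite(p$vlb[j])) addRow(I[j, ], p$vlb[j], ">=")
    }
  }
  ## free-variable split x = xp - xm, xp, xm >= 0
  M <- do.call(rbind, rows)
  Msplit <- cbind(M, -M)
  cc <- c(p$obj, -p$obj)
  if (p$sense == "max") cc <- -cc
  ans <- .simplexCore(cc, Msplit, dir, rhs)
  if (ans$status != "optimal") {
    return(list(status = if (ans$status %in% c("infeasible", "unbounded"))
      ans$status else "error", objective = NA_real_, x = NULL))
  }
  x <- ans$x[seq_len(n)] - ans$x[n + seq_len(n)]
  obj <- sum(p$obj * x)
  viol <- max(0,
              max(p$clb - as.numeric(A %*% x), na.rm = TRUE),
              max(as.numeric(A %*% x) - p$cub, na.rm = TRUE),
              max(p$vlb - x, na.rm = TRUE),
              max(x - p$vub, na.rm = TRUE))
  if (!is.finite(obj) || viol > 1e-6) {
    return(list(status = "error", objective = NA_real_, x = NULL))
  }
  list(status = "optimal", objective = obj, x = x)
}
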