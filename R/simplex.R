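## Two-phase dense simplex for the package's LP core.
##
## Solves   min / max  c' x
##          s.t.  A1 x <= b1,  A2 x >= b2,  A3 x = b3,  x >= 0
## with b1, b2, b3 >= 0 (callers normalize signs). Phase 1 minimizes the sum
## of artificial variables from an all-slack/artificial basis; phase 2
## optimizes c over the feasible basis. The entering rule is Dantzig's (most
## negative reduced cost, ties to the lowest column index); if the iteration
## budget is exhausted - which essentially only happens under degenerate
## cycling - the solve restarts the phase under Bland's rule, which cannot
## cycle. All tie-breaks are index-based, so the returned vertex is
## deterministic.
##
## Returns list(solved = 1 | 0 | -1 | -2, x, value): 1 optimal, -1
## infeasible, -2 unbounded, 0 iteration limit even under Bland's rule.

simplex_lp <- function(a, A1 = NULL, b1 = NULL, A2 = NULL, b2 = NULL,
                       A3 = NULL, b3 = NULL, maximize = FALSE,
                       tol = 1e-9) {
  n <- length(a)
  n1 <- length(b1); n2 <- length(b2); n3 <- length(b3)
  m <- n1 + n2 + n3
  A <- rbind(A1, A2, A3)
  b <- c(b1, b2, b3)
  stopifnot(ncol(A) == n, all(b >= 0))

  ## columns: x (n) | slacks for <= (n1) | surplus for >= (n2) |
  ##          artificials for >= and = (n2 + n3)
  n_art <- n2 + n3
  ncolT <- n + n1 + n2 + n_art
  T <- matrix(0, m, ncolT + 1)
  T[, seq_len(n)] <- A
  T[, ncolT + 1] <- b
  if (n1) for (i in seq_len(n1)) T[i, n + i] <- 1
  if (n2) for (i in seq_len(n2)) T[n1 + i, n + n1 + i] <- -1
  art_cols <- integer(0)
  if (n_art) {
    for (i in seq_len(n_art)) T[n1 + i, n + n1 + n2 + i] <- 1
    art_cols <- n + n1 + n2 + seq_len(n_art)
  }
  basis <- c(if (n1) n + seq_len(n1), art_cols)

  scale <- max(1, max(abs(b)))

  ## ---- phase 1 ----
  if (n_art) {
    c1 <- numeric(ncolT); c1[art_cols] <- 1
    ph1 <- simplex_iterate(T, basis, c1, allowed = rep(TRUE, ncolT), tol = tol)
    if (ph1$status != 1) return(list(solved = 0, x = NULL, value = NA_real_))
    T <- ph1$T; basis <- ph1$basis
    ph1_val <- sum(T[basis %in% art_cols, ncolT + 1])
    if (ph1_val > 1e-7 * scale) {
      return(list(solved = -1, x = NULL, value = NA_real_))
    }
    ## drive remaining (zero-level) artificials out of the basis
    drop_rows <- integer(0)
    for (i in which(basis %in% art_cols)) {
      piv <- which(abs(T[i, seq_len(n + n1 + n2)]) > 1e-8)
      if (length(piv)) {
        T <- simplex_pivot(T, i, piv[1])
        basis[i] <- piv[1]
      } else {
        drop_rows <- c(drop_rows, i)  # redundant constraint row
      }
    }
    if (length(drop_rows)) {
      T <- T[-drop_rows, , drop = FALSE]
      basis <- basis[-drop_rows]
    }
  }

  ## ---- phase 2 ----
  c2 <- numeric(ncolT)
  c2[seq_len(n)] <- if (maximize) -a else a
  allowed <- rep(TRUE, ncolT)
  allowed[art_cols] <- FALSE
  ph2 <- simplex_iterate(T, basis, c2, allowed = allowed, tol = tol)
  if (ph2$status == -2) return(list(solved = -2, x = NULL, value = NA_real_))
  if (ph2$status != 1) return(list(solved = 0, x = NULL, value = NA_real_))
  T <- ph2$T; basis <- ph2$basis

  x <- numeric(ncolT)
  x[basis] <- T[, ncolT + 1]
  xv <- x[seq_len(n)]
  val <- sum(a * xv)
  list(solved = 1, x = xv, value = val)
}

## Pivot the tableau on (row, col).
simplex_pivot <- function(T, row, col) {
  T[row, ] <- T[row, ] / T[row, col]
  other <- setdiff(seq_len(nrow(T)), row)
  fac <- T[other, col]
  nz <- which(abs(fac) > 0)
  if (length(nz)) {
    T[other[nz], ] <- T[other[nz], , drop = FALSE] -
      outer(fac[nz], T[row, ])
  }
  T
}

## Run simplex iterations to optimality for cost vector cc (minimize).
## status: 1 optimal, -2 unbounded, 0 iteration limit (after Bland retry).
simplex_iterate <- function(T, basis, cc, allowed, tol) {
  m <- nrow(T)
  ncolT <- length(cc)
  rhs_col <- ncolT + 1
  max_iter <- 200L * (m + ncolT)
  bland <- FALSE

  for (round in 1:2) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) break
      cB <- cc[basis]
      red <- cc - as.numeric(crossprod(cB, T[, seq_len(ncolT), drop = FALSE]))
      cand <- which(allowed & red < -tol)
      if (!length(cand)) {
        return(list(status = 1, T = T, basis = basis))
      }
      j <- if (bland) cand[1] else cand[which.min(red[cand])]
      col <- T[, j]
      pos <- which(col > tol)
      if (!length(pos)) {
        return(list(status = -2, T = T, basis = basis))
      }
      ratio <- T[pos, rhs_col] / col[pos]
      best <- min(ratio)
      ties <- pos[ratio <= best + 1e-12]
      leave <- ties[which.min(basis[ties])]
      T <- simplex_pivot(T, leave, j)
      basis[leave] <- j
    }
    bland <- TRUE  # retry the phase under Bland's rule (anti-cycling)
  }
  list(status = 0, T = T, basis = basis)
}
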