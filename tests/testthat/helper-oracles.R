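# Independent oracles used to check the LP core and the rank test. These
# deliberately share no code with the package's solvers: linear programs are
# checked by enumerating basic solutions (vertices), the weighted-L1
# minimum by enumerating vertices of the lifted epigraph (kink hyperplanes
# v_r = 0 added as candidate active sets), and the Mann-Whitney test by full
# enumeration of group labelings.

## Enumerate candidate basic points of {Aeq v = beq, Aineq v <= bineq} given
## a list of candidate active hyperplanes (rows (a, b) meaning a.v = b).
## Returns a matrix of feasible points (possibly 0 rows).
enumerate_basic_points <- function(Aeq, beq, Aineq, bineq, cand_A, cand_b,
                                   tol = 1e-7) {
  n <- ncol(cand_A)
  rank_eq <- if (length(beq)) qr(Aeq)$rank else 0
  d <- n - rank_eq
  pts <- list()
  if (d == 0) {
    sol <- tryCatch(qr.solve(Aeq, beq, tol = 1e-10), error = function(e) NULL)
    if (!is.null(sol)) pts[[1]] <- sol
  } else {
    combos <- utils::combn(nrow(cand_A), d)
    for (ci in seq_len(ncol(combos))) {
      idx <- combos[, ci]
      M <- rbind(Aeq, cand_A[idx, , drop = FALSE])
      rhs <- c(beq, cand_b[idx])
      qrM <- qr(M)
      if (qrM$rank < n) next
      sol <- tryCatch(qr.coef(qr(M), rhs), error = function(e) NULL)
      if (is.null(sol) || any(is.na(sol))) next
      if (max(abs(M %*% sol - rhs)) > tol) next
      pts[[length(pts) + 1]] <- as.numeric(sol)
    }
  }
  if (!length(pts)) return(matrix(0, 0, n))
  P <- do.call(rbind, pts)
  ok <- apply(P, 1, function(v) {
    (!length(beq) || max(abs(Aeq %*% v - beq)) <= tol) &&
      all(Aineq %*% v <= bineq + tol)
  })
  P[ok, , drop = FALSE]
}

## Bound-inequality system of a network (v_r <= ub, -v_r <= -lb).
network_ineq <- function(net) {
  n <- length(net$reactions)
  A <- rbind(diag(n), -diag(n))
  b <- c(net$upper_bound, -net$lower_bound)
  list(A = A, b = b)
}

## Max of c.v over {S v = 0, lb <= v <= ub} by vertex enumeration.
oracle_lp_max <- function(net, objective) {
  S <- stoich_matrix(net)
  n <- length(net$reactions)
  cv <- numeric(n); names(cv) <- net$reactions
  cv[names(objective)] <- objective
  iq <- network_ineq(net)
  P <- enumerate_basic_points(S, rep(0, nrow(S)), iq$A, iq$b, iq$A, iq$b)
  if (!nrow(P)) return(NULL)  # infeasible
  max(P %*% cv)
}

## Min of sum(w |v|) over {S v = 0, bounds, v_obj >= fraction * Z} by
## enumerating basic points with the kink hyperplanes v_r = 0 included.
oracle_min_weighted_l1 <- function(net, w, fraction, Z) {
  S <- stoich_matrix(net)
  n <- length(net$reactions)
  obj_i <- match(net$objective, net$reactions)
  iq <- network_ineq(net)
  floor_row <- numeric(n); floor_row[obj_i] <- -1
  Aineq <- rbind(iq$A, floor_row)
  bineq <- c(iq$b, -fraction * Z)
  kinks <- diag(n)
  cand_A <- rbind(Aineq, kinks)
  cand_b <- c(bineq, rep(0, n))
  P <- enumerate_basic_points(S, rep(0, nrow(S)), Aineq, bineq, cand_A, cand_b)
  if (!nrow(P)) return(NULL)
  wv <- w[net$reactions]
  min(abs(P) %*% wv)
}

## Exact two-sided Mann-Whitney by enumerating all group labelings.
oracle_mw_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  comb <- c(x, y)
  u_stat <- function(ix) {
    r <- rank(comb)
    sum(r[ix]) - nx * (nx + 1) / 2
  }
  u_obs <- u_stat(seq_len(nx))
  labelings <- utils::combn(nx + ny, nx)
  us <- apply(labelings, 2, function(ix) {
    r <- rank(comb)
    sum(r[ix]) - nx * (nx + 1) / 2
  })
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(U = u_obs, p = min(1, p))
}

## Random small network for LP oracle tests: always feasible (0 is interior
## to the bounds) and bounded. Metabolite count chosen to keep the free
## dimension small enough for enumeration.
random_oracle_network <- function(seed, n_max = 10) {
  set.seed(seed)
  n <- sample(4:n_max, 1)
  m <- n - sample(2:3, 1)
  m <- max(2, m)
  repeat {
    S <- matrix(sample(c(-2, -1, 0, 0, 1, 2), m * n, replace = TRUE), m, n)
    ## full row rank keeps the free dimension at <= 3 so vertex enumeration
    ## stays exhaustive yet fast
    if (all(colSums(abs(S)) > 0) && all(rowSums(abs(S)) > 0) &&
        qr(S)$rank == m) break
  }
  mets <- sprintf("m%d", seq_len(m))
  rxns <- sprintf("r%d", seq_len(n))
  dimnames(S) <- list(mets, rxns)
  stoich <- lapply(rxns, function(r) {
    col <- S[, r]
    col[col != 0]
  })
  names(stoich) <- rxns
  lb <- stats::setNames(sample(c(0, -5), n, replace = TRUE), rxns)
  ub <- stats::setNames(sample(c(5, 10), n, replace = TRUE), rxns)
  metabolic_network(
    reactions = rxns, stoichiometry = stoich, lower_bound = lb,
    upper_bound = ub, objective = sample(rxns, 1)
  )
}
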