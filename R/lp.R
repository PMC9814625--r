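#' Numerical settings for the LP core
#'
#' @param feasibility_tolerance Pivoting/feasibility tolerance of the LP
#'   solver (default 1e-9).
#' @param mass_balance_tolerance Largest acceptable |S v| residual per
#'   metabolite in a returned flux distribution (default 1e-6).
#' @param parsimony_slack Relative slack on the minimized weighted flux sum
#'   when it is carried forward as a cap constraint: the cap is
#'   `(1 + parsimony_slack) * parsimony_value`. The slack exists only to
#'   keep the optimal face strictly feasible under round-off; it must stay
#'   well below `pruning_tolerance / parsimony_value`, because a reaction
#'   with weight w can carry up to `parsimony_slack * parsimony_value / w`
#'   spurious flux inside the cap. Default 1e-9.
#' @param pruning_tolerance Absolute flux below which a reaction's whole
#'   variability range counts as zero during contextualization (default
#'   1e-6).
#' @return A list of class `lp_settings`.
#' @export
lp_settings <- function(feasibility_tolerance = 1e-9,
                        mass_balance_tolerance = 1e-6,
                        parsimony_slack = 1e-9,
                        pruning_tolerance = 1e-6) {
  s <- list(
    feasibility_tolerance = feasibility_tolerance,
    mass_balance_tolerance = mass_balance_tolerance,
    parsimony_slack = parsimony_slack,
    pruning_tolerance = pruning_tolerance
  )
  for (nm in names(s)) {
    v <- s[[nm]]
    if (!is_scalar_number(v) || v <= 0 || v >= 1e-3) {
      cf_abort(sprintf("%s must be in (0, 1e-3)", nm), "bad_settings")
    }
  }
  structure(s, class = "lp_settings")
}

#' Linear or weighted-absolute-value flux constraint
#'
#' Represents `sum(coef * v) + sum(abs_coef * |v|) (dir) rhs`, used for the
#' fraction-of-optimum constraint (`coef` on the objective reaction) and for
#' the parsimony cap (`abs_coef` = transcript weights).
#'
#' @param coef Named numeric vector of linear coefficients on fluxes.
#' @param abs_coef Named non-negative numeric vector of coefficients on
#'   absolute fluxes.
#' @param dir One of `"<="`, `">="`, `"="`.
#' @param rhs Right-hand side.
#' @return A list of class `flux_constraint`.
#' @export
flux_constraint <- function(coef = NULL, abs_coef = NULL,
                            dir = c("<=", ">=", "="), rhs) {
  dir <- match.arg(dir)
  if (is.null(coef) && is.null(abs_coef)) {
    cf_abort("flux_constraint needs coef and/or abs_coef", "bad_constraint")
  }
  if (!is.null(abs_coef) && any(abs_coef < 0)) {
    cf_abort("abs_coef must be non-negative", "bad_constraint")
  }
  structure(list(coef = coef, abs_coef = abs_coef, dir = dir, rhs = rhs),
            class = "flux_constraint")
}

## Bound used in place of infinite reaction bounds so the LP stays finite;
## an optimum pinned against it is reported as unbounded.
.lp_big <- 1e6

## Build the split-variable LP system shared by fba/fva/pfba:
## x = (vf, vb), v = vf - vb, vf, vb >= 0.
build_lp_system <- function(network, constraints = list()) {
  rxns <- network$reactions
  n <- length(rxns)
  S <- stoich_matrix(network)
  lb <- network$lower_bound
  ub <- network$upper_bound

  capped <- any(!is.finite(lb)) || any(!is.finite(ub))
  lb <- pmax(lb, -.lp_big)
  ub <- pmin(ub, .lp_big)

  ubf <- pmax(ub, 0)
  ubb <- pmax(-lb, 0)

  ## variable upper bounds as <= rows
  A1 <- diag(2 * n)
  b1 <- c(ubf, ubb)

  ## strictly positive lower bounds (and strictly negative upper bounds)
  A2 <- NULL
  b2 <- NULL
  pos_lb <- which(lb > 0)
  for (i in pos_lb) {
    row <- numeric(2 * n); row[i] <- 1; row[n + i] <- -1
    A2 <- rbind(A2, row); b2 <- c(b2, lb[i])
  }
  neg_ub <- which(ub < 0)
  for (i in neg_ub) {
    row <- numeric(2 * n); row[i] <- -1; row[n + i] <- 1
    A2 <- rbind(A2, row); b2 <- c(b2, -ub[i])
  }

  A3 <- cbind(S, -S)
  b3 <- rep(0, nrow(S))

  for (con in constraints) {
    cv <- numeric(n); names(cv) <- rxns
    ca <- numeric(n); names(ca) <- rxns
    if (!is.null(con$coef)) cv[names(con$coef)] <- con$coef
    if (!is.null(con$abs_coef)) ca[names(con$abs_coef)] <- con$abs_coef
    row <- c(cv + ca, -cv + ca)
    rhs <- con$rhs
    dir <- con$dir
    if (rhs < 0) {  # boot::simplex needs non-negative right-hand sides
      row <- -row; rhs <- -rhs
      dir <- switch(dir, "<=" = ">=", ">=" = "<=", "=" = "=")
    }
    if (dir == "<=") {
      A1 <- rbind(A1, row); b1 <- c(b1, rhs)
    } else if (dir == ">=") {
      A2 <- rbind(A2, row); b2 <- c(b2, rhs)
    } else {
      A3 <- rbind(A3, row); b3 <- c(b3, rhs)
    }
  }

  ## Drop linearly dependent equality rows (e.g. metabolites of an internal
  ## loop whose balance rows mirror each other): redundant equalities break
  ## the simplex phase-1 pivoting. Reduction is on the augmented matrix
  ## [A3 | b3], so an inconsistent dependent row stays and is reported as
  ## infeasible by the solver rather than silently dropped.
  if (length(b3) > 1) {
    aug <- cbind(A3, b3)
    dec <- qr(t(aug))
    keep_rows <- sort(dec$pivot[seq_len(dec$rank)])
    A3 <- A3[keep_rows, , drop = FALSE]
    b3 <- b3[keep_rows]
  }

  list(n = n, rxns = rxns, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
       A3 = A3, b3 = b3, capped = capped)
}

## Solve over a prebuilt system. objective/l1_weights are named vectors on
## fluxes; the l1 part is only meaningful when minimizing.
solve_lp_system <- function(sys, objective = NULL, l1_weights = NULL,
                            maximize = FALSE, settings = lp_settings()) {
  n <- sys$n
  cv <- numeric(n); names(cv) <- sys$rxns
  if (!is.null(objective)) cv[names(objective)] <- objective
  w <- numeric(n); names(w) <- sys$rxns
  if (!is.null(l1_weights)) w[names(l1_weights)] <- l1_weights
  a <- c(cv + w, -cv + w)

  res <- simplex_lp(
    a = a, A1 = sys$A1, b1 = sys$b1, A2 = sys$A2, b2 = sys$b2,
    A3 = sys$A3, b3 = sys$b3, maximize = maximize,
    tol = settings$feasibility_tolerance
  )
  if (res$solved == -1) {
    cf_abort("linear program is infeasible", "lp_infeasible")
  }
  if (res$solved == -2) {
    cf_abort("objective is unbounded", "lp_unbounded")
  }
  if (res$solved == 0) {
    cf_abort("LP iteration limit reached", "lp_iteration_limit")
  }
  x <- as.numeric(res$x)
  v <- x[seq_len(n)] - x[n + seq_len(n)]
  names(v) <- sys$rxns
  if (sys$capped && any(abs(v) >= 0.999 * .lp_big)) {
    cf_abort("objective is unbounded (flux pinned at the internal cap)",
             "lp_unbounded")
  }
  list(v = v, value = as.numeric(res$value),
       objective_value = sum(cv * v), l1_value = sum(w * abs(v)))
}
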