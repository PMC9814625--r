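#' Sample feasible flux vectors from a contextualized model
#'
#' Artificial-centering hit-and-run sampling over the patient's constrained
#' flux polytope: steady-state mass balance on the retained reactions
#' (pruned reactions are fixed at zero), the reaction bounds, the
#' fraction-of-optimum floor on the objective, and the parsimony cap
#' `sum(w |v|) <= (1 + slack) * parsimony_value`. The walk starts at the
#' parsimonious flux vector projected onto the mass-balance null space,
#' moves along directions drawn from the null space (after burn-in,
#' artificial-centering directions through previously accepted points), and
#' keeps every `thin`-th point after `burn_in` steps. The weighted-L1 cap is
#' convex, so its feasible stretch along any chord is an interval, located
#' exactly via the piecewise-linear breakpoints.
#'
#' A zero-volume polytope (a fully pinned model) yields `n` copies of the
#' parsimonious vertex with a warning.
#'
#' @param ctx A `contextualized_model` from [contextualize()].
#' @param network The [metabolic_network()] that `ctx` was built from.
#' @param n Number of samples, in \[50, 500\] (see [choose_sample_count()]).
#' @param seed Integer seed; the returned matrix is reproducible from it.
#' @param settings [lp_settings()].
#' @param burn_in,thin Markov-chain burn-in steps and thinning interval.
#' @return A `flux_sample_set`: patient id and group, `reactions` (the
#'   retained reaction order), `samples` (an `n` x length(reactions)
#'   matrix), `n`, and `seed`.
#' @export
sample_fluxes <- function(ctx, network, n, seed, settings = lp_settings(),
                          burn_in = 100L, thin = 10L) {
  stopifnot(inherits(ctx, "contextualized_model"))
  if (!is_count(n) || n < 50 || n > 500) {
    cf_abort("n must be an integer in [50, 500]", "bad_sample_count")
  }
  retained <- ctx$retained
  if (!all(retained %in% network$reactions)) {
    cf_abort("contextualized model does not match this network",
             "network_mismatch")
  }
  S <- stoich_matrix(network)[, retained, drop = FALSE]
  lb <- network$lower_bound[retained]
  ub <- network$upper_bound[retained]
  w <- ctx$weights[retained]
  cap <- (1 + settings$parsimony_slack) * ctx$parsimony_value
  obj_floor <- ctx$fraction * ctx$objective_value
  obj_idx <- match(network$objective, retained)

  ## Directions must stay inside the affine hull of the polytope, which is
  ## lower-dimensional than the null space of S wherever the contextual
  ## constraints pin a flux (FVA width ~ 0): otherwise every random chord
  ## immediately hits a wall. Pinned reactions are added as equality rows.
  widths <- ctx$flux_ranges[retained, "max"] - ctx$flux_ranges[retained, "min"]
  pinned <- which(widths <= settings$pruning_tolerance)
  E <- S
  for (i in pinned) {
    row <- numeric(length(retained)); row[i] <- 1
    E <- rbind(E, row)
  }
  N <- MASS::Null(t(E))
  if (!is.matrix(N)) N <- matrix(N, ncol = if (length(N)) 1 else 0)

  ## start at the parsimonious vertex, projected onto the mass-balance null
  ## space so the (tiny) fluxes of pruned reactions do not leave a residual
  N0 <- MASS::Null(t(S))
  if (!is.matrix(N0)) N0 <- matrix(N0, ncol = if (length(N0)) 1 else 0)
  v0 <- ctx$pfba_flux[retained]
  v0 <- as.numeric(N0 %*% crossprod(N0, v0))
  names(v0) <- retained

  degenerate <- ncol(N) == 0L
  if (!degenerate) {
    samples <- withr::with_seed(seed, achr_walk(
      v0, N, lb, ub, w, cap, obj_idx, obj_floor, n, burn_in, thin
    ))
    if (is.null(samples)) degenerate <- TRUE
  }
  if (degenerate) {
    warning(sprintf(
      "patient '%s': zero-volume flux polytope; returning %d copies of the parsimonious vertex",
      ctx$patient_id, n
    ))
    samples <- matrix(rep(v0, each = n), nrow = n)
  }
  colnames(samples) <- retained

  structure(
    list(patient_id = ctx$patient_id, group = ctx$group,
         reactions = retained, samples = samples, n = as.integer(n),
         seed = as.integer(seed)),
    class = "flux_sample_set"
  )
}

#' @export
print.flux_sample_set <- function(x, ...) {
  cat(sprintf("Flux sample set for '%s' (%s): %d samples x %d reactions (seed %d)\n",
              x$patient_id, x$group, x$n, length(x$reactions), x$seed))
  invisible(x)
}

## The hit-and-run walk, parameterized in null-space coordinates
## (x = v0 + N z) so mass balance holds exactly at every step instead of
## drifting over thousands of additions. Returns NULL if no usable chord is
## ever found (caller treats that as a degenerate polytope).
achr_walk <- function(v0, N, lb, ub, w, cap, obj_idx, obj_floor,
                      n, burn_in, thin) {
  k <- ncol(N)
  z <- numeric(k)
  z_center <- numeric(k)
  n_accepted <- 0L
  kept <- matrix(NA_real_, n, length(v0))
  n_kept <- 0L
  total_steps <- burn_in + n * thin
  moved <- FALSE
  anchors <- list()

  for (step in seq_len(total_steps)) {
    ## direction: random null-space vector during burn-in, then
    ## artificial-centering (through a random earlier point)
    dz <- if (step <= burn_in || length(anchors) < 2L || stats::runif(1) < 0.1) {
      stats::rnorm(k)
    } else {
      anchors[[sample.int(length(anchors), 1)]] - z_center
    }
    nd <- sqrt(sum(dz * dz))
    if (nd < 1e-12) next
    dz <- dz / nd

    x <- v0 + as.numeric(N %*% z)
    d <- as.numeric(N %*% dz)
    chord <- chord_interval(x, d, lb, ub, w, cap, obj_idx, obj_floor)
    if (is.null(chord) || chord[2] - chord[1] < 1e-11) next
    t <- stats::runif(1, chord[1], chord[2])
    z <- z + t * dz
    moved <- TRUE
    n_accepted <- n_accepted + 1L
    z_center <- z_center + (z - z_center) / (n_accepted + 1)
    if (length(anchors) < 50L) {
      anchors[[length(anchors) + 1L]] <- z
    } else {
      anchors[[sample.int(50L, 1)]] <- z
    }
    if (step > burn_in && (step - burn_in) %% thin == 0L) {
      n_kept <- n_kept + 1L
      kept[n_kept, ] <- v0 + as.numeric(N %*% z)
      if (n_kept == n) break
    }
  }
  if (!moved) return(NULL)
  ## if thinning positions were skipped (chords too short), pad with the
  ## last accepted point
  if (n_kept < n) {
    for (i in seq(n_kept + 1L, n)) kept[i, ] <- v0 + as.numeric(N %*% z)
  }
  kept
}

## Feasible interval [a, b] (a <= 0 <= b) for x + t d under box bounds, the
## objective floor, and the convex weighted-L1 cap.
chord_interval <- function(x, d, lb, ub, w, cap, obj_idx, obj_floor) {
  tlo <- -Inf
  thi <- Inf
  nz <- which(abs(d) > 1e-14)
  if (length(nz)) {
    t1 <- (lb[nz] - x[nz]) / d[nz]
    t2 <- (ub[nz] - x[nz]) / d[nz]
    lohi <- pmin(t1, t2)
    hihi <- pmax(t1, t2)
    tlo <- max(tlo, max(lohi))
    thi <- min(thi, min(hihi))
  }
  if (abs(d[obj_idx]) > 1e-14) {
    tt <- (obj_floor - x[obj_idx]) / d[obj_idx]
    if (d[obj_idx] > 0) tlo <- max(tlo, tt) else thi <- min(thi, tt)
  } else if (x[obj_idx] < obj_floor - 1e-9) {
    return(NULL)
  }
  if (!is.finite(tlo) || !is.finite(thi) || tlo > thi) return(NULL)

  l1 <- l1_interval(x, d, w, cap, tlo, thi)
  if (is.null(l1)) return(NULL)
  c(max(tlo, l1[1]), min(thi, l1[2]))
}

## {t in [tlo, thi] : g(t) = sum(w |x + t d|) <= cap} for convex
## piecewise-linear g with g(0) <= cap (x is feasible). Exact via the
## breakpoints t_r = -x_r / d_r.
l1_interval <- function(x, d, w, cap, tlo, thi) {
  act <- which(w > 0)
  if (!length(act)) return(c(tlo, thi))
  g <- function(t) sum(w[act] * abs(x[act] + t * d[act]))
  if (g(0) > cap + 1e-9 * max(1, cap)) return(NULL)

  bp <- -x[act] / d[act]
  bp <- bp[is.finite(bp)]
  up <- sort(unique(c(bp[bp > 0 & bp < thi], thi)))
  dn <- sort(unique(c(bp[bp < 0 & bp > tlo], tlo)), decreasing = TRUE)

  upper <- thi
  prev <- 0
  for (t in up) {
    if (g(t) > cap) {
      ## crossing in (prev, t]: g linear there
      g1 <- g(prev); g2 <- g(t)
      upper <- prev + (cap - g1) / (g2 - g1) * (t - prev)
      break
    }
    prev <- t
    upper <- t
  }
  lower <- tlo
  prev <- 0
  for (t in dn) {
    if (g(t) > cap) {
      g1 <- g(prev); g2 <- g(t)
      lower <- prev + (cap - g1) / (g2 - g1) * (t - prev)
      break
    }
    prev <- t
    lower <- t
  }
  c(lower, upper)
}

#' Check sampled flux vectors against their constraints
#'
#' Verifies, row by row, that a [sample_fluxes()] result satisfies mass
#' balance, the reaction bounds, the fraction-of-optimum floor, and the
#' parsimony cap within the given tolerances.
#'
#' @param sample_set A `flux_sample_set`.
#' @param ctx The `contextualized_model` it was drawn from.
#' @param network The underlying [metabolic_network()].
#' @param settings [lp_settings()].
#' @param tol Extra absolute tolerance for the bound/floor/cap checks.
#' @return List with `ok` (logical, all rows feasible) and `n_feasible`.
#' @export
validate_flux_samples <- function(sample_set, ctx, network,
                                  settings = lp_settings(), tol = 1e-6) {
  retained <- sample_set$reactions
  S <- stoich_matrix(network)[, retained, drop = FALSE]
  lb <- network$lower_bound[retained]
  ub <- network$upper_bound[retained]
  w <- ctx$weights[retained]
  cap <- (1 + settings$parsimony_slack) * ctx$parsimony_value
  floor_val <- ctx$fraction * ctx$objective_value
  obj <- match(network$objective, retained)

  feasible <- apply(sample_set$samples, 1, function(v) {
    max(abs(S %*% v)) <= settings$mass_balance_tolerance &&
      all(v >= lb - tol) && all(v <= ub + tol) &&
      v[obj] >= floor_val - tol &&
      sum(w * abs(v)) <= cap + tol * max(1, cap)
  })
  list(ok = all(feasible), n_feasible = sum(feasible),
       n = nrow(sample_set$samples))
}
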