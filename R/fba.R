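#' Flux balance analysis
#'
#' Maximizes flux through the network's objective reaction subject to
#' steady-state mass balance (`S v = 0`) and the reaction bounds, and
#' returns one optimal flux distribution. Degenerate alternate optima are a
#' property of the model; which optimal vertex is returned is deterministic
#' for a given network but solver-defined, so downstream pruning relies on
#' flux variability analysis rather than on this single vertex.
#'
#' @param network A [metabolic_network()].
#' @param settings [lp_settings()].
#' @return A `flux_distribution`: list with `flux` (named vector) and
#'   `objective_value`.
#' @export
fba <- function(network, settings = lp_settings()) {
  validate_network(network)
  sys <- build_lp_system(network)
  obj <- stats::setNames(1, network$objective)
  sol <- solve_lp_system(sys, objective = obj, maximize = TRUE,
                         settings = settings)
  flux_distribution(network, sol$v, sol$objective_value, settings)
}

flux_distribution <- function(network, v, objective_value, settings) {
  resid <- max(abs(stoich_matrix(network) %*% v))
  if (resid > settings$mass_balance_tolerance) {
    warning(sprintf("mass-balance residual %.3g exceeds tolerance", resid))
  }
  structure(
    list(flux = v, objective_value = objective_value),
    class = "flux_distribution"
  )
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("Flux distribution: %d reactions, objective value %.6g\n",
              length(x$flux), x$objective_value))
  invisible(x)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum attainable flux under mass balance, the
#' reaction bounds, and any extra constraints (e.g. a fraction-of-optimum
#' floor and a parsimony cap). Used to find reactions that cannot carry flux
#' in a constrained state.
#'
#' @param network A [metabolic_network()].
#' @param extra_constraints List of [flux_constraint()] objects.
#' @param reactions Reaction ids to analyze (default: all).
#' @param settings [lp_settings()].
#' @return A numeric matrix with one row per reaction and columns
#'   `min`, `max`.
#' @export
fva <- function(network, extra_constraints = list(),
                reactions = network$reactions, settings = lp_settings()) {
  validate_network(network)
  unknown <- setdiff(reactions, network$reactions)
  if (length(unknown)) {
    cf_abort(sprintf("unknown reaction id: %s", unknown[1]), "unknown_reaction")
  }
  sys <- build_lp_system(network, extra_constraints)
  out <- matrix(NA_real_, length(reactions), 2,
                dimnames = list(reactions, c("min", "max")))
  for (r in reactions) {
    obj <- stats::setNames(1, r)
    lo <- solve_lp_system(sys, obj, maximize = FALSE, settings = settings)
    hi <- solve_lp_system(sys, obj, maximize = TRUE, settings = settings)
    out[r, ] <- c(
      min(lo$objective_value, hi$objective_value),
      max(lo$objective_value, hi$objective_value)
    )
  }
  out
}

#' Transcript-weighted parsimonious FBA
#'
#' Two-stage parsimonious FBA with per-reaction weights: first the plain FBA
#' optimum Z of the objective is computed, then total weighted absolute flux
#' `sum(w_r |v_r|)` is minimized subject to mass balance, bounds, and
#' `v_objective >= fraction * Z`. Each reversible reaction is split into
#' non-negative forward and backward parts, which linearizes the weighted-L1
#' objective exactly. With all weights equal to 1 this is classical pFBA;
#' with transcript-derived weights (see [abundance_to_weights()]) flux is
#' steered through transcriptionally supported reactions.
#'
#' @param network A [metabolic_network()].
#' @param weights Named non-negative weight per reaction (missing reactions
#'   default to 1; `NULL` means classical pFBA with unit weights).
#' @param fraction Required fraction of the FBA optimum, in (0, 1]. The
#'   default 1.0 forces full objective attainment; 0.8 reproduces the usual
#'   RIPTiDe default.
#' @param settings [lp_settings()].
#' @return List with `flux` (a `flux_distribution` at the parsimonious
#'   optimum), `parsimony_value` (the minimized weighted flux sum), and
#'   `fba_objective` (Z).
#' @export
weighted_pfba <- function(network, weights = NULL, fraction = 1,
                          settings = lp_settings()) {
  if (!is_scalar_number(fraction) || fraction <= 0 || fraction > 1) {
    cf_abort("fraction must be in (0, 1]", "bad_fraction")
  }
  validate_network(network)
  w <- stats::setNames(rep(1, length(network$reactions)), network$reactions)
  if (!is.null(weights)) {
    unknown <- setdiff(names(weights), network$reactions)
    if (length(unknown)) {
      cf_abort(sprintf("weight for unknown reaction: %s", unknown[1]),
               "unknown_reaction")
    }
    if (any(weights < 0)) cf_abort("weights must be >= 0", "bad_weights")
    w[names(weights)] <- weights
  }

  opt <- fba(network, settings)
  Z <- opt$objective_value
  if (Z <= 0) {
    cf_abort(sprintf("FBA optimum is %.3g; parsimonious analysis needs a positive objective", Z),
             "nonpositive_objective")
  }

  floor_con <- flux_constraint(
    coef = stats::setNames(1, network$objective), dir = ">=",
    rhs = fraction * Z
  )
  sys <- build_lp_system(network, list(floor_con))
  sol <- solve_lp_system(sys, objective = NULL, l1_weights = w,
                         maximize = FALSE, settings = settings)
  fd <- flux_distribution(network, sol$v,
                          unname(sol$v[network$objective]), settings)
  list(flux = fd, parsimony_value = sol$value, fba_objective = Z,
       weights = w, fraction = fraction)
}
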