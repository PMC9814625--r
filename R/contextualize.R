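#' Build a patient-specific (contextualized) model
#'
#' The transcript-guided pruning stage. For one patient the pipeline is:
#' map gene abundances onto reactions ([reaction_abundance()]), convert them
#' to parsimony weights ([abundance_to_weights()]), solve the
#' transcript-weighted parsimonious FBA ([weighted_pfba()]) at the requested
#' fraction of the objective optimum, then run flux variability analysis
#' under two carried-forward constraints: the objective floor
#' `v_obj >= fraction * Z` and the parsimony cap
#' `sum(w |v|) <= (1 + parsimony_slack) * parsimony_value`. Reactions whose
#' entire variability range lies within the pruning tolerance of zero cannot
#' carry flux in this transcriptomic context and are pruned; the rest are
#' retained with their flux ranges.
#'
#' Pruning is decided by FVA under the parsimony cap, not by the single
#' returned pFBA vertex, so it does not depend on which of several alternate
#' optima the LP solver happens to return.
#'
#' @param network A [metabolic_network()] (after [overlay_genes()]).
#' @param profile A [transcript_profile()].
#' @param fraction Fraction of the FBA optimum to enforce, in (0, 1]
#'   (default 1).
#' @param settings [lp_settings()].
#' @return A `contextualized_model`: patient id and group, `retained` and
#'   `pruned` reaction ids, `flux_ranges` (matrix, retained reactions),
#'   `parsimony_value`, `objective_value` (Z), the transcript `weights`,
#'   `fraction`, and the parsimonious flux vector `pfba_flux`.
#' @export
contextualize <- function(network, profile, fraction = 1,
                          settings = lp_settings()) {
  abund <- reaction_abundance(network, profile)
  weights <- abundance_to_weights(abund)
  pf <- weighted_pfba(network, weights, fraction, settings)

  cons <- contextual_constraints(network, weights, fraction,
                                 pf$fba_objective, pf$parsimony_value,
                                 settings)
  ranges <- fva(network, cons, network$reactions, settings)

  tol <- settings$pruning_tolerance
  blocked <- pmax(abs(ranges[, "min"]), abs(ranges[, "max"])) <= tol
  pruned <- rownames(ranges)[blocked]
  retained <- rownames(ranges)[!blocked]
  if (network$objective %in% pruned) {
    cf_abort("pruning would remove the objective reaction", "objective_removed")
  }

  structure(
    list(
      patient_id = profile$sample_id,
      group = profile$group,
      retained = retained,
      pruned = pruned,
      flux_ranges = ranges[retained, , drop = FALSE],
      parsimony_value = pf$parsimony_value,
      objective_value = pf$fba_objective,
      weights = weights,
      fraction = fraction,
      pfba_flux = pf$flux$flux
    ),
    class = "contextualized_model"
  )
}

## The two constraints every contextualized state must satisfy.
contextual_constraints <- function(network, weights, fraction, Z,
                                   parsimony_value, settings) {
  list(
    flux_constraint(coef = stats::setNames(1, network$objective),
                    dir = ">=", rhs = fraction * Z),
    flux_constraint(abs_coef = weights, dir = "<=",
                    rhs = (1 + settings$parsimony_slack) * parsimony_value)
  )
}

#' @export
print.contextualized_model <- function(x, ...) {
  cat(sprintf(
    "Contextualized model for '%s' (%s): %d retained, %d pruned\n",
    x$patient_id, x$group, length(x$retained), length(x$pruned)
  ))
  cat(sprintf("  objective %.6g, parsimony value %.6g, fraction %.2f\n",
              x$objective_value, x$parsimony_value, x$fraction))
  invisible(x)
}

#' Number of flux samples for a contextualized model
#'
#' The sampler draws between 50 and 500 flux vectors depending on how much
#' room the permissible flux ranges leave: the count is the mean flux-range
#' width across retained reactions, rounded and clamped into \[50, 500\].
#' Wide ranges (many attainable states) earn more samples; a nearly pinned
#' model gets the floor of 50.
#'
#' @param flux_ranges Matrix with `min`/`max` columns, as in a
#'   `contextualized_model`.
#' @return Integer sample count in \[50, 500\].
#' @export
choose_sample_count <- function(flux_ranges) {
  widths <- flux_ranges[, "max"] - flux_ranges[, "min"]
  n <- round(mean(widths))
  as.integer(min(500, max(50, n)))
}
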