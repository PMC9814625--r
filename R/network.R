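#' Construct a metabolic network
#'
#' The in-memory representation of a constraint-based metabolic model: a set
#' of metabolites, a set of reactions with stoichiometry, flux bounds,
#' optional GPR rules and subsystem labels, and a declared objective
#' (biomass) reaction. This is the stoichiometric matrix S plus bound
#' vectors that flux balance analysis operates on under the steady-state
#' assumption S v = 0.
#'
#' @param reactions Character vector of unique reaction ids.
#' @param stoichiometry Named list (one element per reaction) of named
#'   numeric vectors mapping metabolite ids to signed coefficients
#'   (negative = consumed, positive = produced).
#' @param lower_bound,upper_bound Named numeric vectors of flux bounds per
#'   reaction (same flux units throughout, conventionally mmol/gDW/h).
#'   Missing entries default to the community convention -1000/1000 for
#'   reversible and 0/1000 for irreversible use; here any reaction without
#'   explicit bounds gets \[-1000, 1000\].
#' @param objective Reaction id of the objective (biomass) reaction.
#' @param gpr Named list of GPR trees ([parse_gpr()]) or rule strings;
#'   reactions without an entry get the empty rule.
#' @param subsystem Named character vector of subsystem labels; reactions
#'   without an entry get the empty label `""`.
#' @param metabolites Optional character vector of metabolite ids; defaults
#'   to the metabolites referenced by the stoichiometry.
#' @return An object of class `metabolic_network`.
#' @examples
#' net <- metabolic_network(
#'   reactions = c("EX_A", "R1", "R_bio"),
#'   stoichiometry = list(
#'     EX_A = c(A = 1), R1 = c(A = -1, B = 1), R_bio = c(B = -1)
#'   ),
#'   lower_bound = c(EX_A = 0, R1 = 0, R_bio = 0),
#'   upper_bound = c(EX_A = 10, R1 = 1000, R_bio = 1000),
#'   objective = "R_bio"
#' )
#' net
#' @export
metabolic_network <- function(reactions, stoichiometry, lower_bound = NULL,
                              upper_bound = NULL, objective, gpr = list(),
                              subsystem = character(), metabolites = NULL) {
  reactions <- as.character(reactions)
  lb <- rep(-1000, length(reactions))
  ub <- rep(1000, length(reactions))
  names(lb) <- names(ub) <- reactions
  if (!is.null(lower_bound)) lb[names(lower_bound)] <- as.double(lower_bound)
  if (!is.null(upper_bound)) ub[names(upper_bound)] <- as.double(upper_bound)

  gpr_list <- stats::setNames(vector("list", length(reactions)), reactions)
  for (r in names(gpr)) {
    g <- gpr[[r]]
    if (is.character(g)) g <- parse_gpr(g)
    gpr_list[[r]] <- g
  }

  subsys <- stats::setNames(rep("", length(reactions)), reactions)
  if (length(subsystem)) {
    subsystem <- subsystem[!is.na(subsystem)]
    subsys[names(subsystem)] <- as.character(subsystem)
  }

  stoichiometry <- stoichiometry[reactions]
  mets_used <- sort(unique(unlist(lapply(stoichiometry, names))))
  if (is.null(metabolites)) {
    metabolites <- mets_used
  } else {
    metabolites <- as.character(metabolites)
  }

  net <- structure(
    list(
      metabolites = metabolites,
      reactions = reactions,
      stoichiometry = stoichiometry,
      lower_bound = lb,
      upper_bound = ub,
      gpr = gpr_list,
      subsystem = subsys,
      objective = objective
    ),
    class = "metabolic_network"
  )
  validate_network(net)
  net
}

#' Validate a metabolic network
#'
#' Checks the structural invariants: unique reaction and metabolite ids,
#' every referenced metabolite declared, `lower_bound <= upper_bound` for
#' every reaction, and a declared objective that exists in the network.
#'
#' @param network A `metabolic_network`.
#' @return The network, invisibly; errors describe the offending element.
#' @export
validate_network <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  rxns <- network$reactions
  if (anyDuplicated(rxns)) {
    cf_abort(
      sprintf("duplicate reaction id: %s", rxns[duplicated(rxns)][1]),
      "network_invalid"
    )
  }
  if (anyDuplicated(network$metabolites)) {
    cf_abort(
      sprintf("duplicate metabolite id: %s",
              network$metabolites[duplicated(network$metabolites)][1]),
      "network_invalid"
    )
  }
  if (is.null(network$objective) || !nzchar(network$objective %||% "")) {
    cf_abort("no objective declared", "network_no_objective")
  }
  if (!network$objective %in% rxns) {
    cf_abort(
      sprintf("objective reaction '%s' not in the network", network$objective),
      "network_no_objective"
    )
  }
  bad <- rxns[network$lower_bound[rxns] > network$upper_bound[rxns]]
  if (length(bad)) {
    cf_abort(
      sprintf("reaction '%s' has lower_bound > upper_bound", bad[1]),
      "network_invalid"
    )
  }
  for (r in rxns) {
    mets <- names(network$stoichiometry[[r]])
    if (is.null(mets) || !length(mets)) {
      cf_abort(sprintf("reaction '%s' has empty stoichiometry", r),
               "network_invalid")
    }
    miss <- setdiff(mets, network$metabolites)
    if (length(miss)) {
      cf_abort(
        sprintf("reaction '%s' references undeclared metabolite '%s'",
                r, miss[1]),
        "network_invalid"
      )
    }
  }
  invisible(network)
}

#' @export
print.metabolic_network <- function(x, ...) {
  n_gpr <- sum(!vapply(x$gpr, is.null, logical(1)))
  cat(sprintf(
    "Metabolic network: %d reactions, %d metabolites\n",
    length(x$reactions), length(x$metabolites)
  ))
  cat(sprintf("  objective: %s\n", x$objective))
  cat(sprintf("  gene-associated reactions: %d (%d genes)\n",
              n_gpr, length(model_genes(x))))
  subs <- unique(x$subsystem[nzchar(x$subsystem)])
  cat(sprintf("  subsystems: %d\n", length(subs)))
  invisible(x)
}

#' Stoichiometric matrix of a network
#'
#' @param network A `metabolic_network`.
#' @return A dense numeric matrix S (metabolites x reactions).
#' @export
stoich_matrix <- function(network) {
  S <- matrix(0, length(network$metabolites), length(network$reactions),
              dimnames = list(network$metabolites, network$reactions))
  for (r in network$reactions) {
    st <- network$stoichiometry[[r]]
    S[names(st), r] <- st
  }
  S
}

#' Genes of a network
#'
#' @param network A `metabolic_network`.
#' @return Sorted unique gene ids appearing in any GPR rule.
#' @export
model_genes <- function(network) {
  sort(unique(unlist(lapply(network$gpr, gpr_genes))))
}

#' Remove reactions from a network
#'
#' Returns a new network without the listed reactions. Metabolites no longer
#' referenced by any surviving reaction are dropped. Bounds, stoichiometry,
#' GPR rules and subsystems of the surviving reactions are untouched. The
#' objective reaction cannot be removed.
#'
#' @param network A `metabolic_network`.
#' @param ids Character vector of reaction ids to remove (may be empty).
#' @return The reduced `metabolic_network`.
#' @export
remove_reactions <- function(network, ids) {
  stopifnot(inherits(network, "metabolic_network"))
  ids <- as.character(ids)
  unknown <- setdiff(ids, network$reactions)
  if (length(unknown)) {
    cf_abort(sprintf("unknown reaction id: %s", unknown[1]), "unknown_reaction")
  }
  if (network$objective %in% ids) {
    cf_abort(
      sprintf("cannot remove the objective reaction '%s'", network$objective),
      "objective_removed"
    )
  }
  keep <- setdiff(network$reactions, ids)
  stoich <- network$stoichiometry[keep]
  mets <- sort(unique(unlist(lapply(stoich, names))))

  net <- structure(
    list(
      metabolites = mets,
      reactions = keep,
      stoichiometry = stoich,
      lower_bound = network$lower_bound[keep],
      upper_bound = network$upper_bound[keep],
      gpr = network$gpr[keep],
      subsystem = network$subsystem[keep],
      objective = network$objective
    ),
    class = "metabolic_network"
  )
  validate_network(net)
  net
}
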