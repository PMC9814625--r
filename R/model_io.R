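#' Read a genome-scale metabolic model
#'
#' Reads a constraint-based model from disk. COBRA-JSON is the canonical
#' dialect (read and write, round-trip safe); SBML Level 3 with the `fbc`
#' package is supported read-only. The objective is taken from the reaction
#' with a non-zero `objective_coefficient` (COBRA-JSON) or from the active
#' `fbc:objective` (SBML).
#'
#' Reactions without a subsystem annotation get the empty label. Reactions
#' without explicit bounds get the community default of -1000 (lower) and
#' 1000 (upper).
#'
#' @param path Path to a model file.
#' @param format `"auto"` (by file extension), `"cobra-json"` or `"sbml"`.
#' @return A validated [metabolic_network()].
#' @seealso [write_model()]
#' @export
load_model <- function(path, format = c("auto", "cobra-json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    cf_abort(sprintf("model file not found: %s", path), "file_not_found")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xml", "sbml")) "sbml" else "cobra-json"
  }
  switch(format,
    "cobra-json" = load_cobra_json(path),
    "sbml" = load_sbml(path)
  )
}

load_cobra_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      cf_abort(sprintf("malformed COBRA-JSON in '%s': %s", path,
                       conditionMessage(e)), "model_parse_error")
    }
  )
  if (is.null(doc$reactions)) {
    cf_abort(sprintf("malformed COBRA-JSON in '%s': no 'reactions' element",
                     path), "model_parse_error")
  }

  mets <- vapply(doc$metabolites %||% list(), function(m) {
    m$id %||% cf_abort("metabolite without an 'id'", "model_parse_error")
  }, character(1))

  rxn_ids <- character(0)
  stoich <- list()
  lb <- ub <- numeric(0)
  gpr <- list()
  subsys <- character(0)
  obj_id <- NULL
  for (rx in doc$reactions) {
    id <- rx$id
    if (is.null(id)) {
      cf_abort(sprintf("reaction without an 'id' in '%s'", path),
               "model_parse_error")
    }
    st <- unlist(rx$metabolites)
    if (is.null(st) || !length(st)) {
      cf_abort(sprintf("reaction '%s' has no metabolites", id),
               "model_parse_error")
    }
    rxn_ids <- c(rxn_ids, id)
    stoich[[id]] <- st
    lb[[id]] <- as.double(rx$lower_bound %||% -1000)
    ub[[id]] <- as.double(rx$upper_bound %||% 1000)
    rule <- rx$gene_reaction_rule %||% ""
    gpr[[id]] <- parse_gpr(rule)
    subsys[[id]] <- as.character(rx$subsystem %||% "")
    oc <- as.double(rx$objective_coefficient %||% 0)
    if (!is.na(oc) && oc != 0) obj_id <- id
  }
  if (is.null(obj_id)) cf_abort("no objective declared", "network_no_objective")

  metabolic_network(
    reactions = rxn_ids, stoichiometry = stoich, lower_bound = lb,
    upper_bound = ub, objective = obj_id, gpr = gpr, subsystem = subsys,
    metabolites = if (length(mets)) mets else NULL
  )
}

#' Write a network as COBRA-JSON
#'
#' Serializes a [metabolic_network()] to the COBRA-JSON dialect. A write
#' followed by [load_model()] reproduces the network exactly (ids, order,
#' stoichiometry, bounds, GPR semantics, subsystems).
#'
#' @param network A `metabolic_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(network, path) {
  validate_network(network)
  rxns <- lapply(network$reactions, function(r) {
    list(
      id = r,
      metabolites = as.list(network$stoichiometry[[r]]),
      lower_bound = network$lower_bound[[r]],
      upper_bound = network$upper_bound[[r]],
      gene_reaction_rule = gpr_to_string(network$gpr[[r]]),
      subsystem = network$subsystem[[r]],
      objective_coefficient = if (r == network$objective) 1 else 0
    )
  })
  genes <- lapply(model_genes(network), function(g) list(id = g))
  doc <- list(
    id = "contextflux_model",
    metabolites = lapply(network$metabolites, function(m) list(id = m)),
    reactions = rxns,
    genes = genes
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## -- SBML Level 3 / FBC reader (read-only) ----------------------------------

load_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    cf_abort(sprintf("malformed SBML in '%s': %s", path, conditionMessage(e)),
             "model_parse_error")
  })
  ## namespace-agnostic element lookup (core + fbc namespaces vary by file)
  ln <- function(...) {
    paste(vapply(c(...), function(x) sprintf("*[local-name()='%s']", x),
                 character(1)), collapse = "/")
  }

  boundary <- character(0)
  met_nodes <- xml2::xml_find_all(doc, paste0(".//", ln("listOfSpecies", "species")))
  mets <- xml2::xml_attr(met_nodes, "id")
  bc <- xml2::xml_attr(met_nodes, "boundaryCondition")
  boundary <- mets[!is.na(bc) & bc == "true"]
  mets <- setdiff(mets, boundary)

  ## fbc flux bounds are indirected through global parameters
  par_nodes <- xml2::xml_find_all(doc, paste0(".//", ln("listOfParameters", "parameter")))
  par_val <- stats::setNames(
    as.double(xml2::xml_attr(par_nodes, "value")),
    xml2::xml_attr(par_nodes, "id")
  )

  ## gene products: GPR leaves reference fbc ids; prefer the label
  gp_nodes <- xml2::xml_find_all(doc, paste0(".//", ln("listOfGeneProducts", "geneProduct")))
  gp_label <- stats::setNames(
    xml2::xml_attr(gp_nodes, "label"),
    xml2::xml_attr(gp_nodes, "id")
  )
  gp_label[is.na(gp_label)] <- names(gp_label)[is.na(gp_label)]

  rxn_nodes <- xml2::xml_find_all(doc, paste0(".//", ln("listOfReactions", "reaction")))
  if (!length(rxn_nodes)) {
    cf_abort(sprintf("malformed SBML in '%s': no reactions", path),
             "model_parse_error")
  }
  rxn_ids <- character(0)
  stoich <- list()
  lb <- ub <- numeric(0)
  gpr <- list()
  for (node in rxn_nodes) {
    id <- xml2::xml_attr(node, "id")
    st <- numeric(0)
    add_species <- function(sr, sign) {
      sp <- xml2::xml_attr(sr, "species")
      if (sp %in% boundary) return()
      coef <- xml2::xml_attr(sr, "stoichiometry")
      coef <- if (is.na(coef)) 1 else as.double(coef)
      prev <- if (sp %in% names(st)) st[[sp]] else 0
      st[[sp]] <<- prev + sign * coef
    }
    for (sr in xml2::xml_find_all(node, paste0("./", ln("listOfReactants", "speciesReference")))) {
      add_species(sr, -1)
    }
    for (sr in xml2::xml_find_all(node, paste0("./", ln("listOfProducts", "speciesReference")))) {
      add_species(sr, 1)
    }
    if (!length(st)) next  # pure boundary reaction with no internal species
    rxn_ids <- c(rxn_ids, id)
    stoich[[id]] <- st

    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb[[id]] <- if (!is.na(lb_ref) && lb_ref %in% names(par_val)) {
      par_val[[lb_ref]]
    } else if (rev) -1000 else 0
    ub[[id]] <- if (!is.na(ub_ref) && ub_ref %in% names(par_val)) {
      par_val[[ub_ref]]
    } else 1000

    gpa <- xml2::xml_find_first(node, paste0("./", ln("geneProductAssociation")))
    if (!inherits(gpa, "xml_missing")) {
      gpr[[id]] <- sbml_gpa_tree(xml2::xml_child(gpa), gp_label)
    }
  }

  obj_node <- xml2::xml_find_first(doc, paste0(".//", ln("fluxObjective")))
  if (inherits(obj_node, "xml_missing")) {
    cf_abort("no objective declared", "network_no_objective")
  }
  obj_id <- xml2::xml_attr(obj_node, "reaction")

  metabolic_network(
    reactions = rxn_ids, stoichiometry = stoich, lower_bound = lb,
    upper_bound = ub, objective = obj_id, gpr = gpr,
    metabolites = mets
  )
}

sbml_gpa_tree <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    lab <- gp_label[[ref]] %||% ref
    return(list(type = "gene", gene = lab))
  }
  if (nm %in% c("and", "or")) {
    kids <- lapply(xml2::xml_children(node), sbml_gpa_tree, gp_label = gp_label)
    return(gpr_node(nm, kids))
  }
  cf_abort(sprintf("unsupported geneProductAssociation element '%s'", nm),
           "model_parse_error")
}
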