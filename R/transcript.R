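#' Per-sample transcript profiles
#'
#' A transcript profile holds one sample's gene abundances (RPKM-like,
#' non-negative, any consistent scale) plus its group label. Profiles are
#' what the contextualization stage consumes, one patient at a time.
#'
#' @param sample_id Sample identifier.
#' @param group `"case"` or `"control"`.
#' @param abundance Named non-negative numeric vector (gene id -> abundance).
#' @return An object of class `transcript_profile`.
#' @export
transcript_profile <- function(sample_id, group, abundance) {
  group <- match.arg(group, c("case", "control"))
  if (is.null(names(abundance)) || any(!nzchar(names(abundance)))) {
    cf_abort("abundance must be a named vector of gene abundances",
             "bad_profile")
  }
  names(abundance) <- trimws(names(abundance))
  if (anyDuplicated(names(abundance))) {
    cf_abort(
      sprintf("duplicated gene '%s' in sample '%s'",
              names(abundance)[duplicated(names(abundance))][1], sample_id),
      "duplicate_gene"
    )
  }
  if (any(is.na(abundance)) || any(abundance < 0)) {
    bad <- names(abundance)[which(is.na(abundance) | abundance < 0)][1]
    cf_abort(
      sprintf("negative or missing abundance for gene '%s' in sample '%s'",
              bad, sample_id),
      "negative_abundance"
    )
  }
  structure(
    list(sample_id = as.character(sample_id), group = group,
         abundance = abundance),
    class = "transcript_profile"
  )
}

#' @export
print.transcript_profile <- function(x, ...) {
  cat(sprintf("Transcript profile '%s' (%s): %d genes\n",
              x$sample_id, x$group, length(x$abundance)))
  invisible(x)
}

#' Read a gene-abundance table with group labels
#'
#' Reads a genes-by-samples abundance table (TSV or CSV, gene ids in the
#' first column, one column per sample) and a sample-to-group label map,
#' returning one [transcript_profile()] per sample column. Values must be
#' non-negative; gene ids must be unique. No re-normalization is applied:
#' the table is expected to hold already-normalized (e.g. RPKM) values.
#'
#' @param path Path to the abundance table. Separator is inferred from the
#'   extension (`.csv` -> comma, otherwise tab).
#' @param labels Either a named character vector (sample id -> `"case"` /
#'   `"control"`) or a path to a two-column CSV with columns
#'   `sample_id, group`.
#' @return A list of `transcript_profile` objects, one per sample column.
#' @export
load_abundance_table <- function(path, labels) {
  if (!file.exists(path)) {
    cf_abort(sprintf("abundance table not found: %s", path), "file_not_found")
  }
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) {
    cf_abort("abundance table needs a gene column plus >= 1 sample column",
             "bad_table")
  }
  genes <- trimws(as.character(tab[[1]]))
  if (anyDuplicated(genes)) {
    cf_abort(
      sprintf("duplicated gene row '%s' in %s",
              genes[duplicated(genes)][1], path),
      "duplicate_gene"
    )
  }

  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    lab_tab <- utils::read.csv(labels, stringsAsFactors = FALSE)
    labels <- stats::setNames(lab_tab$group, lab_tab$sample_id)
  }

  samples <- colnames(tab)[-1]
  unlabeled <- setdiff(samples, names(labels))
  if (length(unlabeled)) {
    cf_abort(sprintf("sample '%s' has no group label", unlabeled[1]),
             "unlabeled_sample")
  }
  lapply(samples, function(s) {
    transcript_profile(s, labels[[s]], stats::setNames(as.double(tab[[s]]), genes))
  })
}

#' Overlay transcriptomic genes onto a model
#'
#' Implements the gene-overlap pruning step: genes present in both the model
#' and the abundance data are retained, all other model genes are treated as
#' absent, and every reaction whose GPR rule evaluates to FALSE under that
#' presence set is removed from the network. "Present" is structural -- the
#' gene has a row in the table, whatever its value -- so the step removes
#' unmeasured genes, not lowly expressed ones. Reactions without a GPR rule
#' are always retained.
#'
#' @param network A [metabolic_network()].
#' @param profiles List of [transcript_profile()]s sharing one gene universe.
#' @return List with `network` (the reduced model) and `report`, an
#'   `overlay_report` with the overlap counts (model genes, data genes,
#'   shared, data-only, model-only) and the removed reaction ids.
#' @export
overlay_genes <- function(network, profiles) {
  validate_network(network)
  if (!length(profiles)) cf_abort("need at least one profile", "bad_profile")
  gene_sets <- lapply(profiles, function(p) sort(names(p$abundance)))
  if (length(unique(gene_sets)) != 1L) {
    cf_abort("profiles do not share the same gene universe", "bad_profile")
  }
  data_genes <- gene_sets[[1]]
  mod_genes <- model_genes(network)
  present <- intersect(mod_genes, data_genes)

  removed <- network$reactions[!vapply(
    network$gpr[network$reactions], evaluate_gpr_presence, logical(1),
    present_genes = present
  )]
  if (network$objective %in% removed) {
    cf_abort(
      "overlay would remove the objective reaction; model unusable with this data",
      "objective_removed"
    )
  }
  reduced <- remove_reactions(network, removed)

  report <- structure(
    list(
      n_genes_model = length(mod_genes),
      n_genes_data = length(data_genes),
      n_shared = length(present),
      n_data_only = length(setdiff(data_genes, mod_genes)),
      n_model_only = length(setdiff(mod_genes, data_genes)),
      reactions_removed_by_gpr = removed
    ),
    class = "overlay_report"
  )
  list(network = reduced, report = report)
}

#' @export
print.overlay_report <- function(x, ...) {
  cat(sprintf(
    "Gene overlay: %d model genes, %d data genes, %d shared (%d model-only, %d data-only)\n",
    x$n_genes_model, x$n_genes_data, x$n_shared, x$n_model_only, x$n_data_only
  ))
  cat(sprintf("  reactions removed by GPR filtering: %d\n",
              length(x$reactions_removed_by_gpr)))
  invisible(x)
}

#' Map gene abundances onto reactions
#'
#' Evaluates each reaction's GPR rule on a sample's abundances: a leaf takes
#' its gene's abundance (0 if the gene is missing), `and` nodes combine by
#' minimum (an enzyme complex is limited by its scarcest subunit) and `or`
#' nodes by maximum (isozymes add robustness, the most abundant one sets
#' capacity). Reactions without a GPR rule receive the median of the
#' gene-backed reaction abundances for this sample, a neutral value for
#' transport and exchange reactions.
#'
#' @param network A [metabolic_network()] (after [overlay_genes()]).
#' @param profile A [transcript_profile()].
#' @return Named non-negative numeric vector, one value per reaction.
#' @export
reaction_abundance <- function(network, profile) {
  validate_network(network)
  stopifnot(inherits(profile, "transcript_profile"))
  ab <- as.list(profile$abundance)
  vals <- vapply(network$gpr[network$reactions], gpr_abundance, numeric(1),
                 abundance = ab)
  names(vals) <- network$reactions
  backed <- vals[!is.na(vals)]
  fill <- if (length(backed)) stats::median(backed) else 0
  vals[is.na(vals)] <- fill
  vals
}

#' Transcript abundances to parsimony weights
#'
#' Maps per-reaction abundances onto pruning weights `w_r = 1 - a_r /
#' max(a)`: the most abundant reaction costs nothing to use, a reaction with
#' no transcript support costs 1 per flux unit. The map is antitone, so the
#' weighted parsimony objective of [weighted_pfba()] prefers routes through
#' highly expressed enzymes.
#'
#' @param reaction_abund Named non-negative vector from
#'   [reaction_abundance()], with at least one strictly positive entry.
#' @return Named numeric weight vector in \[0, 1\].
#' @export
abundance_to_weights <- function(reaction_abund) {
  if (!length(reaction_abund) || any(reaction_abund < 0)) {
    cf_abort("reaction abundances must be non-negative", "bad_abundance")
  }
  m <- max(reaction_abund)
  if (m <= 0) {
    cf_abort("all reaction abundances are zero: no transcriptomic signal",
             "no_signal")
  }
  1 - reaction_abund / m
}
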