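#' Specification of a synthetic benchmark
#'
#' Parameters of the toy metabolic network and two-group transcriptomic
#' cohort used to exercise the pipeline end to end with known ground truth.
#' The defaults define the package's standard benchmark: two redundant
#' three-reaction pathways to biomass (one favored in cases, one in
#' controls), ten flux-neutral background reactions, 20 patients per group,
#' a fourfold transcript effect on planted pathway genes, and log-normal
#' abundance noise.
#'
#' @param n_linear_pathways Number of alternative pathways to biomass
#'   (default 2; the first is case-favored, the second control-favored).
#' @param pathway_length Reactions per pathway (default 3).
#' @param n_background_reactions Gene-bearing side reactions that cannot
#'   carry steady-state flux toward biomass (default 10).
#' @param n_case,n_control Group sizes (default 20 each).
#' @param effect_fold Fold-change applied to a group's favored pathway genes
#'   (and its reciprocal to the opposing pathway), > 1; default 4.
#'   `effect_fold = 1` gives an exchangeable null cohort.
#' @param noise_sigma Log-normal noise scale on abundances (default 0.5).
#' @param base_abundance Baseline abundance (RPKM-like units, default 10).
#' @param seed Integer seed for cohort simulation (default 1).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_linear_pathways = 2L, pathway_length = 3L,
                           n_background_reactions = 10L, n_case = 20L,
                           n_control = 20L, effect_fold = 4,
                           noise_sigma = 0.5, base_abundance = 10,
                           seed = 1L) {
  spec <- list(
    n_linear_pathways = as.integer(n_linear_pathways),
    pathway_length = as.integer(pathway_length),
    n_background_reactions = as.integer(n_background_reactions),
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    effect_fold = effect_fold, noise_sigma = noise_sigma,
    base_abundance = base_abundance, seed = as.integer(seed)
  )
  counts <- c("n_linear_pathways", "pathway_length", "n_background_reactions",
              "n_case", "n_control")
  for (nm in counts) {
    if (!is_count(spec[[nm]])) cf_abort(sprintf("%s must be >= 1", nm), "bad_spec")
  }
  if (!is_scalar_number(effect_fold) || effect_fold < 1) {
    cf_abort("effect_fold must be >= 1", "bad_spec")
  }
  if (!is_scalar_number(noise_sigma) || noise_sigma <= 0) {
    cf_abort("noise_sigma must be > 0", "bad_spec")
  }
  structure(spec, class = "synthetic_spec")
}

#' Build the toy benchmark network
#'
#' Constructs a small branched network: a bounded uptake reaction
#' (`EX_A`, 0..10) feeding metabolite A, `n_linear_pathways` parallel
#' gene-bearing linear pathways from A to B (one unique gene per reaction,
#' subsystems `"Pathway1"`, `"Pathway2"`, ...), a biomass drain `R_bio`
#' (the objective), and `n_background_reactions` gene-bearing side reactions
#' arranged as internal two-step loops (subsystem `"Background"`) that can
#' never carry net steady-state flux toward biomass. Because the pathways
#' are stoichiometrically redundant routes, which one carries flux is
#' decided purely by the transcript weights -- exactly the situation in
#' which transcript-guided parsimony makes reactions discriminative.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `network` (a [metabolic_network()]) and `truth`, the
#'   ground truth: `planted_case_reactions` (pathway 1, case-favored),
#'   `planted_control_reactions` (pathway 2, control-favored), and
#'   `gene_pathway` (gene -> pathway label map).
#' @export
make_toy_network <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  K <- spec$n_linear_pathways
  L <- spec$pathway_length

  reactions <- "EX_A"
  stoich <- list(EX_A = c(A = 1))
  lb <- c(EX_A = 0)
  ub <- c(EX_A = 10)
  gpr <- list()
  subsys <- c(EX_A = "Transport")
  gene_pathway <- character()

  for (k in seq_len(K)) {
    mets <- c("A", if (L > 1) sprintf("I%d_%d", k, seq_len(L - 1)), "B")
    for (j in seq_len(L)) {
      r <- sprintf("P%d_%d", k, j)
      g <- sprintf("gP%d_%d", k, j)
      reactions <- c(reactions, r)
      stoich[[r]] <- stats::setNames(c(-1, 1), c(mets[j], mets[j + 1]))
      lb[r] <- 0; ub[r] <- 1000
      gpr[[r]] <- parse_gpr(g)
      subsys[r] <- sprintf("Pathway%d", k)
      gene_pathway[g] <- sprintf("Pathway%d", k)
    }
  }

  reactions <- c(reactions, "R_bio")
  stoich$R_bio <- c(B = -1)
  lb["R_bio"] <- 0; ub["R_bio"] <- 1000
  subsys["R_bio"] <- "Biomass"

  for (j in seq_len(spec$n_background_reactions)) {
    pair <- ceiling(j / 2)
    mets <- c(sprintf("C%d", pair), sprintf("D%d", pair))
    r <- sprintf("BG%d", j)
    reactions <- c(reactions, r)
    stoich[[r]] <- if (j %% 2 == 1) {
      stats::setNames(c(-1, 1), mets)
    } else {
      stats::setNames(c(1, -1), mets)
    }
    lb[r] <- 0; ub[r] <- 1000
    gpr[[r]] <- parse_gpr(sprintf("gB%d", j))
    subsys[r] <- "Background"
    gene_pathway[sprintf("gB%d", j)] <- "Background"
  }

  network <- metabolic_network(
    reactions = reactions, stoichiometry = stoich, lower_bound = lb,
    upper_bound = ub, objective = "R_bio", gpr = gpr, subsystem = subsys
  )
  truth <- list(
    planted_case_reactions = grep("^P1_", reactions, value = TRUE),
    planted_control_reactions = if (K >= 2) {
      grep("^P2_", reactions, value = TRUE)
    } else character(),
    gene_pathway = gene_pathway
  )
  list(network = network, truth = truth)
}

#' Simulate a two-group transcriptomic cohort
#'
#' Generates one [transcript_profile()] per patient. Each gene's abundance
#' is `base_abundance * multiplier * exp(N(0, noise_sigma))`, where the
#' multiplier is `effect_fold` for the group's favored pathway genes,
#' `1 / effect_fold` for the opposing pathway's genes, and 1 for all other
#' genes. With `effect_fold = 1` the groups are exchangeable (a null
#' cohort). Reproducible from `spec$seed`.
#'
#' @param network The toy network from [make_toy_network()].
#' @param truth Its ground truth.
#' @param spec A [synthetic_spec()].
#' @return List of `transcript_profile`s (`n_case` cases then `n_control`
#'   controls).
#' @export
simulate_cohort <- function(network, truth, spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- model_genes(network)
  case_genes <- names(truth$gene_pathway)[truth$gene_pathway == "Pathway1"]
  ctrl_genes <- names(truth$gene_pathway)[truth$gene_pathway == "Pathway2"]

  sample_one <- function(id, group) {
    mult <- stats::setNames(rep(1, length(genes)), genes)
    fav <- if (group == "case") case_genes else ctrl_genes
    opp <- if (group == "case") ctrl_genes else case_genes
    mult[intersect(fav, genes)] <- spec$effect_fold
    mult[intersect(opp, genes)] <- 1 / spec$effect_fold
    ab <- spec$base_abundance * mult *
      exp(stats::rnorm(length(genes), 0, spec$noise_sigma))
    transcript_profile(id, group, ab)
  }

  withr::with_seed(spec$seed, {
    c(
      lapply(seq_len(spec$n_case), function(i) {
        sample_one(sprintf("case_%02d", i), "case")
      }),
      lapply(seq_len(spec$n_control), function(i) {
        sample_one(sprintf("control_%02d", i), "control")
      })
    )
  })
}

#' Write a complete synthetic input bundle
#'
#' Materializes a full pipeline input on disk: the toy model as COBRA-JSON,
#' the cohort abundance table as TSV (genes x samples), the sample-to-group
#' label map as CSV, and the ground truth (with the generating parameters
#' and a null-cohort flag) as JSON. Regenerating with the same spec gives
#' byte-identical files.
#'
#' @param outdir Output directory (created if needed).
#' @param spec A [synthetic_spec()].
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixture_bundle <- function(outdir, spec = synthetic_spec()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) {
    cf_abort(sprintf("cannot create output directory '%s'", outdir),
             "unwritable_path")
  }
  toy <- make_toy_network(spec)
  profiles <- simulate_cohort(toy$network, toy$truth, spec)

  paths <- c(
    model = file.path(outdir, "model.json"),
    abundance = file.path(outdir, "abundance.tsv"),
    labels = file.path(outdir, "labels.csv"),
    truth = file.path(outdir, "ground_truth.json")
  )
  write_model(toy$network, paths[["model"]])

  genes <- names(profiles[[1]]$abundance)
  tab <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (p in profiles) tab[[p$sample_id]] <- unname(p$abundance[genes])
  utils::write.table(tab, paths[["abundance"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  labels <- data.frame(
    sample_id = vapply(profiles, function(p) p$sample_id, character(1)),
    group = vapply(profiles, function(p) p$group, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(labels, paths[["labels"]], row.names = FALSE, quote = FALSE)

  jsonlite::write_json(
    list(
      planted_case_reactions = toy$truth$planted_case_reactions,
      planted_control_reactions = toy$truth$planted_control_reactions,
      gene_pathway = as.list(toy$truth$gene_pathway),
      null_cohort = spec$effect_fold == 1,
      spec = unclass(spec)
    ),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
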