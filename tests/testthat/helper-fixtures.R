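# Shared fixtures, built in code.

## The four-reaction toy network: bounded uptake of A, two parallel
## conversions A -> B, and a biomass drain (the objective). The uptake bound
## forces the optimum Z = 10.
t1_network <- function() {
  metabolic_network(
    reactions = c("EX_A", "R1", "R2", "R_bio"),
    stoichiometry = list(
      EX_A = c(A = 1), R1 = c(A = -1, B = 1), R2 = c(A = -1, B = 1),
      R_bio = c(B = -1)
    ),
    lower_bound = c(EX_A = 0, R1 = 0, R2 = 0, R_bio = 0),
    upper_bound = c(EX_A = 10, R1 = 1000, R2 = 1000, R_bio = 1000),
    objective = "R_bio",
    gpr = list(R1 = "g1", R2 = "g2"),
    subsystem = c(EX_A = "Transport", R1 = "PathA", R2 = "PathB",
                  R_bio = "Biomass")
  )
}

## Random GPR tree over genes g1..g<n_genes>.
random_gpr <- function(n_genes = 6, depth = 3) {
  genes <- sprintf("g%d", seq_len(n_genes))
  build <- function(d) {
    if (d == 0 || stats::runif(1) < 0.35) {
      return(list(type = "gene", gene = sample(genes, 1)))
    }
    op <- sample(c("and", "or"), 1)
    k <- sample(2:3, 1)
    contextflux:::gpr_node(op, lapply(seq_len(k), function(i) build(d - 1)))
  }
  build(depth)
}

## Evaluate a GPR rule through an independent route: rewrite it as an R
## boolean (presence) or min/max (abundance) expression and eval() it.
gpr_presence_by_expression <- function(gpr, present) {
  s <- gpr_to_string(gpr)
  if (!nzchar(s)) return(TRUE)
  genes <- gpr_genes(gpr)
  env <- new.env()
  for (g in genes) assign(g, g %in% present, envir = env)
  s <- gsub("\\bor\\b", "||", gsub("\\band\\b", "&&", s))
  eval(parse(text = s), envir = env)
}

gpr_abundance_by_expression <- function(gpr, abund) {
  rewrite <- function(node) {
    if (identical(node$type, "gene")) {
      a <- abund[[node$gene]]
      return(sprintf("%.17g", if (is.null(a)) 0 else a))
    }
    fn <- if (node$type == "and") "min" else "max"
    sprintf("%s(%s)", fn,
            paste(vapply(node$args, rewrite, character(1)), collapse = ", "))
  }
  eval(parse(text = rewrite(gpr)))
}

## A hand-built flux_sample_set (for discriminator tests that do not need
## the LP stage).
fake_sample_set <- function(patient_id, group, reactions, values, n_rows = 60) {
  m <- matrix(rep(values, each = n_rows), nrow = n_rows)
  colnames(m) <- reactions
  structure(
    list(patient_id = patient_id, group = group, reactions = reactions,
         samples = m, n = as.integer(n_rows), seed = 0L),
    class = "flux_sample_set"
  )
}

## A separable two-group cohort of fake sample sets: feature "Rsig" is high
## in cases, zero in controls; "Rnoise" is overlapping noise.
separable_sample_sets <- function(n_per_group = 5, n_rows = 40, seed = 1) {
  set.seed(seed)
  c(
    lapply(seq_len(n_per_group), function(i) {
      s <- fake_sample_set(sprintf("case_%d", i), "case",
                           c("Rsig", "Rnoise", "R_bio"),
                           c(10, stats::runif(1), 5), n_rows)
      s$samples <- s$samples + matrix(stats::rnorm(length(s$samples), 0, 0.05),
                                      nrow = n_rows)
      s
    }),
    lapply(seq_len(n_per_group), function(i) {
      s <- fake_sample_set(sprintf("control_%d", i), "control",
                           c("Rsig", "Rnoise", "R_bio"),
                           c(0, stats::runif(1), 5), n_rows)
      s$samples <- s$samples + matrix(stats::rnorm(length(s$samples), 0, 0.05),
                                      nrow = n_rows)
      s
    })
  )
}

## A small synthetic cohort contextualized end to end (cached per session
## because several test files reuse it).
small_contextualized_cohort <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- synthetic_spec(n_case = 4, n_control = 4, seed = 99)
    toy <- make_toy_network(spec)
    profiles <- simulate_cohort(toy$network, toy$truth, spec)
    contexts <- lapply(profiles, function(p) contextualize(toy$network, p))
    sets <- lapply(seq_along(contexts), function(i) {
      suppressWarnings(sample_fluxes(contexts[[i]], toy$network, n = 50,
                                     seed = 100 + i))
    })
    cache <<- list(spec = spec, network = toy$network, truth = toy$truth,
                   profiles = profiles, contexts = contexts, sets = sets)
    cache
  }
})
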