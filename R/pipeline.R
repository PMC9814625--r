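#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end analysis. The defaults are the
#' workflow's standard constants: full objective
#' attainment (`fraction = 1`, with 0.8 as the usual RIPTiDe default), 100
#' train/test splits at an 80/20 patient ratio, qualification threshold
#' F1 > 0.70, top-20 reaction lists, and raw p < 0.05 significance.
#'
#' @param model,abundance,labels,outdir Input paths (model file, abundance
#'   table, label map) and optional output directory.
#' @param fraction Fraction of the FBA optimum enforced during
#'   contextualization, in (0, 1].
#' @param n_splits Number of repeated train/test splits.
#' @param train_frac Training fraction of patients, in (0, 1).
#' @param f1_min Strict F1 threshold for a split to qualify, in \[0, 1).
#' @param top_k Per-split top list size.
#' @param alpha Significance level for the group comparison.
#' @param master_seed One integer seed; all stage seeds (contextual
#'   sampling, under-sampling, splitting, forests) derive from it.
#' @param settings [lp_settings()].
#' @param rf_params List of random-forest overrides (see [run_split()]).
#' @param pooling `"pooled"` or `"patient_mean"` for [compare_groups()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(model = NULL, abundance = NULL, labels = NULL,
                       outdir = NULL, fraction = 1, n_splits = 100L,
                       train_frac = 0.8, f1_min = 0.70, top_k = 20L,
                       alpha = 0.05, master_seed = 1L,
                       settings = lp_settings(), rf_params = list(),
                       pooling = "pooled") {
  cfg <- list(
    model = model, abundance = abundance, labels = labels, outdir = outdir,
    fraction = fraction, n_splits = n_splits, train_frac = train_frac,
    f1_min = f1_min, top_k = top_k, alpha = alpha,
    master_seed = as.integer(master_seed), settings = settings,
    rf_params = rf_params, pooling = pooling
  )
  check <- function(ok, key, what) {
    if (!ok) cf_abort(sprintf("config key '%s' %s", key, what), "bad_config")
  }
  check(is_scalar_number(fraction) && fraction > 0 && fraction <= 1,
        "fraction", "must be in (0, 1]")
  check(is_scalar_number(train_frac) && train_frac > 0 && train_frac < 1,
        "train_frac", "must be in (0, 1)")
  check(is_scalar_number(f1_min) && f1_min >= 0 && f1_min < 1,
        "f1_min", "must be in [0, 1)")
  check(is_count(n_splits), "n_splits", "must be a positive integer")
  check(is_count(top_k), "top_k", "must be a positive integer")
  check(is_scalar_number(alpha) && alpha >= 0 && alpha <= 1,
        "alpha", "must be in [0, 1]")
  check(pooling %in% c("pooled", "patient_mean"),
        "pooling", "must be 'pooled' or 'patient_mean'")
  structure(cfg, class = "run_config")
}

#' Read and validate a pipeline configuration file
#'
#' Reads a YAML (or JSON) configuration file, fills every unset key with its
#' default, and range-checks the result. An empty file yields the full
#' default configuration.
#'
#' @param path Path to a YAML/JSON config file.
#' @return A validated [run_config()].
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) {
    cf_abort(sprintf("config file not found: %s", path), "file_not_found")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    cf_abort(sprintf("unknown config key '%s'", unknown[1]), "bad_config")
  }
  if (!is.null(raw$settings)) raw$settings <- do.call(lp_settings, raw$settings)
  do.call(run_config, raw)
}

#' Run the full discriminative-reaction pipeline
#'
#' Executes every stage end to end: load the model and abundance table,
#' overlay the data genes onto the model, contextualize each patient
#' (transcript-weighted pFBA + FVA pruning), draw flux samples, assemble the
#' feature matrix, run repeated random-forest validation, aggregate the top
#' discriminative reactions across qualifying splits, compare them between
#' groups with the Mann-Whitney U test, and group them into subsystem
#' families. If no split qualifies (F1 never exceeds `f1_min`), the report
#' carries an empty ranking and a prominent warning instead of aborting.
#'
#' Everything downstream of the inputs is reproducible from
#' `config$master_seed`. If `config$outdir` is set, [render_report()] is
#' called on the result.
#'
#' @param config A [run_config()] (or a path to a config file).
#' @param quiet Suppress per-stage progress messages.
#' @return A `discriminative_report`: `ranking`, `comparisons`, `families`,
#'   `features`, `contexts`, `validation`, `overlay`, and run `metadata`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  t0 <- Sys.time()
  timings <- list()
  clock <- function(stage, expr) {
    s <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    out
  }

  network <- clock("load_model", load_model(config$model))
  profiles <- clock("load_abundance",
                    load_abundance_table(config$abundance, config$labels))
  say("loaded %d reactions, %d profiles", length(network$reactions),
      length(profiles))

  ov <- clock("overlay", overlay_genes(network, profiles))
  net <- ov$network
  say("overlay: %d/%d genes shared; %d reactions removed",
      ov$report$n_shared, ov$report$n_genes_model,
      length(ov$report$reactions_removed_by_gpr))

  contexts <- clock("contextualize", lapply(profiles, function(p) {
    contextualize(net, p, fraction = config$fraction,
                  settings = config$settings)
  }))
  pruned_counts <- vapply(contexts, function(cx) length(cx$pruned), integer(1))
  say("contextualized %d patients; mean reactions pruned %.1f",
      length(contexts), mean(pruned_counts))

  sample_sets <- clock("sample", lapply(seq_along(contexts), function(i) {
    cx <- contexts[[i]]
    n <- choose_sample_count(cx$flux_ranges)
    suppressWarnings(sample_fluxes(
      cx, net, n = n, seed = derive_seed(config$master_seed, 10000L + i),
      settings = config$settings
    ))
  }))
  features <- clock("assemble", assemble_feature_matrix(sample_sets))

  validation <- clock("validate", repeated_validation(
    features, n_splits = config$n_splits, master_seed = config$master_seed,
    train_frac = config$train_frac, rf_params = config$rf_params
  ))
  say("repeated validation: mean accuracy %.3f over %d splits",
      validation$mean_accuracy, config$n_splits)

  ranking <- tryCatch(
    aggregate_top_reactions(validation, f1_min = config$f1_min,
                            k = config$top_k),
    no_qualifying_splits = function(e) {
      warning(sprintf(
        "no qualifying splits (no split reached F1 > %.2f): reporting an empty ranking",
        config$f1_min
      ), call. = FALSE)
      structure(
        list(qualifying_split_ids = integer(),
             ranking = data.frame(reaction = character(),
                                  frequency = integer(),
                                  mean_importance = numeric(),
                                  rank = integer(),
                                  stringsAsFactors = FALSE),
             f1_min = config$f1_min, k = as.integer(config$top_k)),
        class = "aggregated_ranking"
      )
    }
  )

  top <- utils::head(ranking$ranking$reaction, config$top_k)
  comparisons <- if (length(top)) {
    compare_groups(features, top, alpha = config$alpha, mode = config$pooling)
  } else {
    data.frame()
  }
  families <- group_by_subsystem(top, net)

  metadata <- list(
    config = serialize_config(config),
    overlay = unclass(ov$report),
    n_patients = length(contexts),
    mean_reactions_pruned = mean(pruned_counts),
    pruned_per_patient = stats::setNames(
      pruned_counts, vapply(contexts, function(cx) cx$patient_id, character(1))
    ),
    sample_counts = stats::setNames(
      vapply(sample_sets, function(s) s$n, integer(1)),
      vapply(sample_sets, function(s) s$patient_id, character(1))
    ),
    mean_accuracy = validation$mean_accuracy,
    mean_f1 = validation$mean_f1,
    n_qualifying_splits = length(ranking$qualifying_split_ids),
    timings_sec = timings,
    total_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  report <- structure(
    list(ranking = ranking, comparisons = comparisons, families = families,
         features = features, contexts = contexts, validation = validation,
         overlay = ov$report, metadata = metadata),
    class = "discriminative_report"
  )
  if (!is.null(config$outdir)) render_report(report, config$outdir)
  report
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$settings <- unclass(cfg$settings)
  cfg
}

#' @export
print.discriminative_report <- function(x, ...) {
  cat("Discriminative reaction report\n")
  cat(sprintf("  mean accuracy %.3f over %d splits (%d qualifying)\n",
              x$metadata$mean_accuracy, length(x$validation$splits),
              x$metadata$n_qualifying_splits))
  cat(sprintf("  mean reactions pruned per patient: %.1f\n",
              x$metadata$mean_reactions_pruned))
  if (nrow(x$ranking$ranking)) {
    cat("  top reactions:\n")
    print(utils::head(x$ranking$ranking, 5))
  } else {
    cat("  (empty ranking: no qualifying splits)\n")
  }
  invisible(x)
}
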