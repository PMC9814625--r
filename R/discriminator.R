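#' Assemble the flux feature matrix
#'
#' Stacks per-patient flux samples into one machine-learning table. The
#' feature order is the sorted union of retained reactions across patients;
#' a reaction pruned in a given patient's context contributes exactly 0 to
#' that patient's rows (it cannot carry flux there). Every row is labeled
#' with its patient and group.
#'
#' @param sample_sets List of `flux_sample_set` objects ([sample_fluxes()]),
#'   at least two patients per group, unique patient ids.
#' @return A `feature_table`: `features` (reaction ids), `x` (rows x
#'   features matrix), `row_patient`, `row_group`, and `patients` (named
#'   group vector).
#' @export
assemble_feature_matrix <- function(sample_sets) {
  ids <- vapply(sample_sets, function(s) s$patient_id, character(1))
  if (anyDuplicated(ids)) {
    cf_abort(sprintf("duplicate patient id: %s", ids[duplicated(ids)][1]),
             "duplicate_patient")
  }
  groups <- vapply(sample_sets, function(s) s$group, character(1))
  if (sum(groups == "case") < 2 || sum(groups == "control") < 2) {
    cf_abort("need at least two patients per group", "too_few_patients")
  }
  features <- sort(unique(unlist(lapply(sample_sets, function(s) s$reactions))))

  blocks <- lapply(sample_sets, function(s) {
    m <- matrix(0, nrow(s$samples), length(features),
                dimnames = list(NULL, features))
    m[, s$reactions] <- s$samples
    m
  })
  x <- do.call(rbind, blocks)
  n_rows <- vapply(blocks, nrow, integer(1))

  structure(
    list(
      features = features,
      x = x,
      row_patient = rep(ids, n_rows),
      row_group = rep(groups, n_rows),
      patients = stats::setNames(groups, ids)
    ),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "Feature table: %d flux points x %d reactions, %d patients (%d case / %d control)\n",
    nrow(x$x), length(x$features), length(x$patients),
    sum(x$patients == "case"), sum(x$patients == "control")
  ))
  invisible(x)
}

#' Balance groups by random under-sampling of patients
#'
#' Keeps every patient of the minority group and a uniform random subset of
#' equal size from the majority group, so each train/test split sees
#' balanced classes.
#'
#' @param labels Named character vector, patient id -> `"case"`/`"control"`.
#' @param seed Integer seed; the selection is reproducible from it.
#' @return Character vector of selected patient ids.
#' @export
undersample_patients <- function(labels, seed) {
  grp <- split(names(labels), labels)
  if (length(grp) < 2 || any(lengths(grp) == 0)) {
    cf_abort("both groups must be non-empty", "too_few_patients")
  }
  n_min <- min(lengths(grp))
  picked <- withr::with_seed(seed, lapply(grp, function(ids) {
    ids <- sort(ids)
    if (length(ids) == n_min) ids else sort(sample(ids, n_min))
  }))
  unname(unlist(picked))
}

#' Stratified patient-level train/test partition
#'
#' Splits patients (not rows) into train and test sets, stratified by group:
#' per group, `floor(train_frac * n)` patients are drawn for training and
#' the rest go to the test side. Reproducible from `seed`.
#'
#' @param patients Character vector of patient ids (balanced beforehand via
#'   [undersample_patients()]).
#' @param labels Named group vector for those patients.
#' @param train_frac Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with sorted `train` and `test` id vectors.
#' @export
split_patients <- function(patients, labels, train_frac, seed) {
  picked <- withr::with_seed(seed + 1L, {
    unlist(lapply(split(patients, labels[patients]), function(ids) {
      ids <- sort(ids)
      sample(ids, floor(train_frac * length(ids)))
    }))
  })
  train <- sort(unname(picked))
  list(train = train, test = sort(setdiff(patients, train)))
}

#' One train/test split: random forest on flux points
#'
#' Balances the patient set by under-sampling, splits the patients (not the
#' rows) 80/20 stratified by group, trains a random forest (100 trees, Gini
#' impurity, sqrt(p) features per node) on all flux points of the training
#' patients, and evaluates on all flux points of the test patients. Keeping
#' every flux point of a patient on one side of the split prevents the
#' leakage that row-level splitting would allow.
#'
#' @param features A `feature_table`.
#' @param split_id Integer identifier recorded in the result.
#' @param seed Integer seed for under-sampling, the patient split and the
#'   forest.
#' @param train_frac Fraction of patients used for training (default 0.8).
#' @param rf_params List overriding forest parameters (`num.trees`, `mtry`,
#'   `min.node.size`).
#' @param patients Optional pre-selected (balanced) patient ids; by default
#'   [undersample_patients()] is applied with `seed`.
#' @return A `split_result`: split id, train/test patient ids, row-level
#'   `accuracy`, `f1` (harmonic mean of precision and recall, positive class
#'   `"case"`), normalized impurity `importances`, and the seed.
#' @export
run_split <- function(features, split_id, seed, train_frac = 0.8,
                      rf_params = list(), patients = NULL) {
  stopifnot(inherits(features, "feature_table"))
  if (!is_scalar_number(train_frac) || train_frac <= 0 || train_frac >= 1) {
    cf_abort("train_frac must be in (0, 1)", "bad_config")
  }
  if (is.null(patients)) {
    patients <- undersample_patients(features$patients, seed)
  }
  labels <- features$patients[patients]

  parts <- split_patients(patients, labels, train_frac, seed)
  train_patients <- parts$train
  test_patients <- parts$test
  if (!all(c("case", "control") %in% labels[test_patients]) ||
      !all(c("case", "control") %in% labels[train_patients])) {
    cf_abort("a group is absent from one side of the split", "bad_split")
  }

  tr <- features$row_patient %in% train_patients
  te <- features$row_patient %in% test_patients
  stopifnot(!any(tr & te))

  params <- utils::modifyList(
    list(num.trees = 100L, mtry = max(1L, floor(sqrt(length(features$features)))),
         min.node.size = 1L),
    rf_params
  )
  y_train <- factor(features$row_group[tr], levels = c("control", "case"))
  fit <- ranger::ranger(
    x = features$x[tr, , drop = FALSE], y = y_train,
    num.trees = params$num.trees, mtry = params$mtry,
    min.node.size = params$min.node.size,
    importance = "impurity", seed = seed + 2L, num.threads = 1
  )
  pred <- stats::predict(fit, features$x[te, , drop = FALSE],
                         num.threads = 1)$predictions
  truth <- factor(features$row_group[te], levels = c("control", "case"))

  accuracy <- mean(pred == truth)
  tp <- sum(pred == "case" & truth == "case")
  fp <- sum(pred == "case" & truth == "control")
  fn <- sum(pred == "control" & truth == "case")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0

  imp <- fit$variable.importance
  imp[imp < 0] <- 0
  imp <- if (sum(imp) > 0) imp / sum(imp) else {
    stats::setNames(rep(1 / length(imp), length(imp)), names(imp))
  }

  structure(
    list(split_id = as.integer(split_id), train_patients = train_patients,
         test_patients = test_patients, accuracy = accuracy, f1 = f1,
         importances = imp, seed = as.integer(seed)),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("Split %d: accuracy %.3f, F1 %.3f (%d train / %d test patients)\n",
              x$split_id, x$accuracy, x$f1,
              length(x$train_patients), length(x$test_patients)))
  invisible(x)
}

#' Repeated train/test validation
#'
#' Runs `n_splits` independent under-sample + patient-split + train +
#' evaluate cycles. Per-split seeds are derived deterministically from the
#' master seed, so the whole set of results is reproducible from one
#' integer.
#'
#' @param features A `feature_table`.
#' @param n_splits Number of splits (default 100).
#' @param master_seed Integer master seed.
#' @param train_frac,rf_params Passed to [run_split()].
#' @return A `validation_result`: list of `split_result`s plus
#'   `mean_accuracy` and `mean_f1`.
#' @export
repeated_validation <- function(features, n_splits = 100L, master_seed,
                                train_frac = 0.8, rf_params = list()) {
  if (!is_count(n_splits)) cf_abort("n_splits must be >= 1", "bad_config")
  results <- lapply(seq_len(n_splits), function(i) {
    run_split(features, split_id = i, seed = derive_seed(master_seed, i),
              train_frac = train_frac, rf_params = rf_params)
  })
  structure(
    list(
      splits = results,
      mean_accuracy = mean(vapply(results, function(r) r$accuracy, numeric(1))),
      mean_f1 = mean(vapply(results, function(r) r$f1, numeric(1)))
    ),
    class = "validation_result"
  )
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("Repeated validation: %d splits, mean accuracy %.3f, mean F1 %.3f\n",
              length(x$splits), x$mean_accuracy, x$mean_f1))
  invisible(x)
}

#' Aggregate the top discriminative reactions across qualifying splits
#'
#' From every split whose F1 score strictly exceeds `f1_min`, the top `k`
#' reactions by forest importance are extracted. The final ranking orders
#' reactions by how often they appear in a qualifying split's top `k`
#' (descending), breaking ties by mean importance across qualifying splits
#' (descending) and then by reaction id, so the ranking is a deterministic
#' total order.
#'
#' @param results A `validation_result` or a plain list of `split_result`s.
#' @param f1_min Qualification threshold on F1, strict (default 0.70).
#' @param k Per-split top list size (default 20).
#' @return An `aggregated_ranking`: `qualifying_split_ids` and a
#'   `ranking` data frame (reaction, frequency, mean_importance, rank).
#' @export
aggregate_top_reactions <- function(results, f1_min = 0.70, k = 20L) {
  if (inherits(results, "validation_result")) results <- results$splits
  keep <- vapply(results, function(r) r$f1 > f1_min, logical(1))
  if (!any(keep)) {
    cf_abort(
      sprintf("no qualifying splits: no split reached F1 > %.2f", f1_min),
      "no_qualifying_splits"
    )
  }
  qualifying <- results[keep]

  top_lists <- lapply(qualifying, function(r) {
    imp <- r$importances
    ord <- order(-imp, names(imp))
    names(imp)[ord][seq_len(min(k, length(imp)))]
  })
  freq <- table(unlist(top_lists))
  all_feats <- sort(unique(unlist(lapply(qualifying,
                                         function(r) names(r$importances)))))
  imp_mat <- do.call(rbind, lapply(qualifying, function(r) {
    v <- stats::setNames(numeric(length(all_feats)), all_feats)
    v[names(r$importances)] <- r$importances
    v
  }))
  mean_imp <- colMeans(imp_mat)

  reactions <- names(freq)
  df <- data.frame(
    reaction = reactions,
    frequency = as.integer(freq),
    mean_importance = unname(mean_imp[reactions]),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$frequency, -df$mean_importance, df$reaction), ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL

  structure(
    list(
      qualifying_split_ids = vapply(qualifying, function(r) as.integer(r$split_id), integer(1)),
      ranking = df,
      f1_min = f1_min,
      k = as.integer(k)
    ),
    class = "aggregated_ranking"
  )
}

#' @export
print.aggregated_ranking <- function(x, ...) {
  cat(sprintf("Aggregated ranking from %d qualifying splits (F1 > %.2f, top %d):\n",
              length(x$qualifying_split_ids), x$f1_min, x$k))
  print(utils::head(x$ranking, 10))
  invisible(x)
}
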