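test_that("feature assembly unions reactions and zero-fills pruned ones", {
  sets <- list(
    fake_sample_set("P1", "case", c("R1", "R_bio"), c(5, 1), 60),
    fake_sample_set("P2", "case", c("R1", "R_bio"), c(4, 1), 60),
    fake_sample_set("P3", "control", c("R2", "R_bio"), c(7, 1), 50),
    fake_sample_set("P4", "control", c("R2", "R_bio"), c(6, 1), 50)
  )
  ft <- assemble_feature_matrix(sets)
  expect_equal(ft$features, c("R1", "R2", "R_bio"))
  expect_equal(nrow(ft$x), 60 + 60 + 50 + 50)
  # P1 rows have R2 = 0 (pruned there), P3 rows have R1 = 0
  expect_true(all(ft$x[ft$row_patient == "P1", "R2"] == 0))
  expect_true(all(ft$x[ft$row_patient == "P3", "R1"] == 0))
  expect_equal(unname(ft$patients), c("case", "case", "control", "control"))

  expect_error(assemble_feature_matrix(sets[c(1, 1, 3, 4)]),
               class = "duplicate_patient")
  expect_error(assemble_feature_matrix(sets[c(1, 3, 4)]),
               class = "too_few_patients")
})

test_that("under-sampling balances groups and is seed-reproducible", {
  labels <- stats::setNames(
    c(rep("case", 163), rep("control", 42)),
    c(sprintf("cd_%03d", 1:163), sprintf("ct_%02d", 1:42))
  )
  sel <- undersample_patients(labels, seed = 7)
  expect_length(sel, 84)
  expect_equal(sum(labels[sel] == "case"), 42)
  expect_equal(sum(labels[sel] == "control"), 42)
  expect_true(all(names(labels)[labels == "control"] %in% sel))

  expect_identical(sel, undersample_patients(labels, seed = 7))
  expect_false(identical(sel, undersample_patients(labels, seed = 8)))

  balanced <- stats::setNames(rep(c("case", "control"), each = 10),
                              sprintf("p%02d", 1:20))
  expect_setequal(undersample_patients(balanced, 1), names(balanced))

  expect_error(undersample_patients(stats::setNames("case", "p1"), 1),
               class = "too_few_patients")
})

test_that("patient-level splits never leak and stay stratified", {
  labels <- stats::setNames(rep(c("case", "control"), each = 10),
                            sprintf("p%02d", 1:20))
  for (s in 1:50) {
    sel <- undersample_patients(labels, s)
    parts <- split_patients(sel, labels[sel], train_frac = 0.8, seed = s)
    expect_length(intersect(parts$train, parts$test), 0)
    expect_setequal(c(parts$train, parts$test), sel)
    expect_equal(sum(labels[parts$train] == "case"), 8)
    expect_equal(sum(labels[parts$train] == "control"), 8)
  }
})

test_that("a split on separable features reaches perfect accuracy and F1", {
  ft <- assemble_feature_matrix(separable_sample_sets())
  res <- run_split(ft, split_id = 1, seed = 11)
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$f1, 1.0)
  expect_length(intersect(res$train_patients, res$test_patients), 0)
  expect_equal(sum(res$importances), 1.0, tolerance = 1e-9)
  # the informative feature dominates the importances
  expect_equal(names(which.max(res$importances)), "Rsig")

  # determinism in (split_id, seed)
  res2 <- run_split(ft, split_id = 1, seed = 11)
  expect_identical(res[c("accuracy", "f1", "importances", "train_patients")],
                   res2[c("accuracy", "f1", "importances", "train_patients")])
})

test_that("repeated validation derives split seeds from the master seed", {
  ft <- assemble_feature_matrix(separable_sample_sets())
  rv <- repeated_validation(ft, n_splits = 5, master_seed = 42)
  expect_length(rv$splits, 5)
  expect_gte(rv$mean_accuracy, 0.95)

  one <- repeated_validation(ft, n_splits = 1, master_seed = 42)
  direct <- run_split(ft, split_id = 1,
                      seed = contextflux:::derive_seed(42, 1))
  expect_identical(one$splits[[1]]$importances, direct$importances)
  expect_identical(one$splits[[1]]$accuracy, direct$accuracy)

  # distinct splits see distinct patient partitions
  parts <- vapply(rv$splits, function(r) paste(r$test_patients, collapse = ","),
                  character(1))
  expect_gt(length(unique(parts)), 1)
})

test_that("aggregation keeps only strictly qualifying splits with stated tie-breaks", {
  mk_split <- function(id, f1, imps) {
    structure(list(split_id = id, train_patients = "a", test_patients = "b",
                   accuracy = f1, f1 = f1, importances = imps, seed = id),
              class = "split_result")
  }
  imp1 <- c(Rx = 0.5, Ry = 0.3, Rz = 0.2)
  imp2 <- c(Rx = 0.6, Rz = 0.3, Ry = 0.1)
  agg <- aggregate_top_reactions(list(
    mk_split(1, 0.9, imp1), mk_split(2, 0.8, imp2),
    mk_split(3, 0.70, c(Rboundary = 1)),   # F1 == threshold: excluded
    mk_split(4, 0.5, c(Rlow = 1))
  ), f1_min = 0.70, k = 2)
  expect_equal(agg$qualifying_split_ids, c(1L, 2L))
  expect_equal(agg$ranking$reaction[1], "Rx")
  expect_equal(agg$ranking$frequency[1], 2L)
  expect_false("Rboundary" %in% agg$ranking$reaction)
  # Ry and Rz each appear once; mean importance breaks the tie (Rz > Ry)
  expect_equal(agg$ranking$reaction[2:3], c("Rz", "Ry"))

  expect_error(
    aggregate_top_reactions(list(mk_split(1, 0.5, imp1),
                                 mk_split(2, 0.5, imp2))),
    class = "no_qualifying_splits"
  )
})
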