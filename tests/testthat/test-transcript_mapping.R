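make_table <- function(df, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  utils::write.table(df, path, sep = if (ext == ".csv") "," else "\t",
                     quote = FALSE, row.names = FALSE)
  path
}

test_that("abundance tables load into one profile per sample column", {
  tab <- data.frame(gene = c("g1", "g2", "g3"), s1 = c(1, 2, 3),
                    s2 = c(0, 5, 10))
  path <- make_table(tab)
  profiles <- load_abundance_table(path, c(s1 = "case", s2 = "control"))
  expect_length(profiles, 2)
  expect_equal(profiles[[1]]$sample_id, "s1")
  expect_equal(profiles[[2]]$group, "control")
  expect_equal(profiles[[2]]$abundance, c(g1 = 0, g2 = 5, g3 = 10))

  # negative value rejected, naming gene and sample
  tab$s1[2] <- -1
  expect_error(
    load_abundance_table(make_table(tab), c(s1 = "case", s2 = "control")),
    regexp = "g2.*s1"
  )

  # duplicated gene row rejected by name
  tab2 <- data.frame(gene = c("g1", "g1"), s1 = c(1, 2))
  expect_error(load_abundance_table(make_table(tab2), c(s1 = "case")),
               regexp = "g1")

  # unlabeled sample rejected
  tab3 <- data.frame(gene = "g1", s1 = 1, s2 = 2)
  expect_error(load_abundance_table(make_table(tab3), c(s1 = "case")),
               class = "unlabeled_sample")

  # labels can come from a two-column csv file
  lab <- make_table(data.frame(sample_id = c("s1", "s2"),
                               group = c("case", "control")), ".csv")
  tab$s1[2] <- 2
  profiles2 <- load_abundance_table(make_table(tab), lab)
  expect_equal(vapply(profiles2, `[[`, "", "group"), c("case", "control"))
})

test_that("gene overlay removes GPR-unsupported reactions and counts overlap", {
  net <- metabolic_network(
    reactions = c("u", "ra", "rb", "rc", "obj"),
    stoichiometry = list(u = c(A = 1), ra = c(A = -1, B = 1),
                         rb = c(A = -1, B = 1), rc = c(A = -1, B = 1),
                         obj = c(B = -1)),
    lower_bound = c(u = 0, ra = 0, rb = 0, rc = 0, obj = 0),
    upper_bound = c(u = 10, ra = 10, rb = 10, rc = 10, obj = 10),
    objective = "obj",
    gpr = list(ra = "g1", rb = "g2", rc = "g2 or g1")
  )
  prof <- transcript_profile("s1", "case", c(g1 = 1, g3 = 2, g9 = 5))
  ov <- overlay_genes(net, list(prof))

  # model genes {g1,g2}, data genes {g1,g3,g9}: shared = {g1}
  expect_equal(ov$report$n_genes_model, 2)
  expect_equal(ov$report$n_genes_data, 3)
  expect_equal(ov$report$n_shared, 1)
  expect_equal(ov$report$n_data_only, 2)
  expect_equal(ov$report$n_model_only, 1)
  expect_equal(ov$report$reactions_removed_by_gpr, "rb")
  # OR rule with one present gene is retained; empty GPR retained
  expect_setequal(ov$network$reactions, c("u", "ra", "rc", "obj"))

  # data superset of model genes: nothing removed
  prof2 <- transcript_profile("s2", "case", c(g1 = 1, g2 = 0, extra = 3))
  ov2 <- overlay_genes(net, list(prof2))
  expect_length(ov2$report$reactions_removed_by_gpr, 0)

  # idempotence: overlaying again changes nothing
  ov3 <- overlay_genes(ov$network, list(prof))
  expect_equal(ov3$network$reactions, ov$network$reactions)
  expect_length(ov3$report$reactions_removed_by_gpr, 0)
})

test_that("overlay refuses to remove the objective reaction", {
  net <- metabolic_network(
    reactions = c("u", "obj"),
    stoichiometry = list(u = c(A = 1), obj = c(A = -1)),
    lower_bound = c(u = 0, obj = 0), upper_bound = c(u = 10, obj = 10),
    objective = "obj", gpr = list(obj = "gene_absent")
  )
  prof <- transcript_profile("s1", "case", c(g1 = 1))
  expect_error(overlay_genes(net, list(prof)), class = "objective_removed")
})

test_that("reaction abundance follows min/max GPR semantics with median fill", {
  net <- metabolic_network(
    reactions = c("u", "r1", "r2", "r3", "obj"),
    stoichiometry = list(u = c(A = 1), r1 = c(A = -1, B = 1),
                         r2 = c(A = -1, B = 1), r3 = c(A = -1, B = 1),
                         obj = c(B = -1)),
    lower_bound = c(u = 0, r1 = 0, r2 = 0, r3 = 0, obj = 0),
    upper_bound = c(u = 10, r1 = 10, r2 = 10, r3 = 10, obj = 10),
    objective = "obj",
    gpr = list(r1 = "(g1 and g2) or g3", r2 = "g4", r3 = "g5")
  )
  prof <- transcript_profile(
    "s", "case", c(g1 = 4, g2 = 10, g3 = 3, g4 = 7.5, g5 = 2)
  )
  ab <- reaction_abundance(net, prof)
  expect_equal(ab[["r1"]], max(min(4, 10), 3))  # = 4
  expect_equal(ab[["r2"]], 7.5)
  # empty-GPR reactions get the median of gene-backed scores {4, 7.5, 2}
  expect_equal(ab[["u"]], 4)
  expect_equal(ab[["obj"]], 4)
  # absent gene counts as zero
  prof2 <- transcript_profile("s2", "case", c(g3 = 3, g4 = 1, g5 = 1))
  expect_equal(reaction_abundance(net, prof2)[["r1"]], 3)
})

test_that("abundance evaluation agrees with independent min/max expression", {
  set.seed(5)
  for (i in 1:40) {
    tree <- random_gpr(n_genes = 6, depth = 3)
    ab <- as.list(stats::setNames(round(stats::runif(6, 0, 20), 3),
                                  sprintf("g%d", 1:6)))
    expect_equal(contextflux:::gpr_abundance(tree, ab),
                 gpr_abundance_by_expression(tree, ab))
  }
})

test_that("weight map is the antitone 1 - a/max formula onto [0,1]", {
  expect_equal(abundance_to_weights(c(r1 = 10, r2 = 5, r3 = 0)),
               c(r1 = 0, r2 = 0.5, r3 = 1))
  expect_equal(abundance_to_weights(c(r1 = 3, r2 = 3)), c(r1 = 0, r2 = 0))
  expect_error(abundance_to_weights(c(r1 = 0, r2 = 0)), class = "no_signal")

  set.seed(3)
  for (i in 1:200) {
    a <- stats::runif(sample(2:10, 1), 0, 100)
    names(a) <- sprintf("r%d", seq_along(a))
    w <- abundance_to_weights(a)
    expect_true(all(w >= 0 & w <= 1))
    # antitone: higher abundance never gets the larger weight
    ord <- order(a)
    expect_true(all(diff(w[ord]) <= 1e-12))
  }
})
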