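test_that("network construction enforces the structural invariants", {
  net <- t1_network()
  expect_s3_class(net, "metabolic_network")
  expect_equal(length(net$reactions), 4)
  expect_setequal(net$metabolites, c("A", "B"))

  expect_error(
    metabolic_network(
      reactions = c("r1", "r1"),
      stoichiometry = list(r1 = c(A = 1)), objective = "r1"
    ),
    class = "network_invalid"
  )
  expect_error(
    metabolic_network(
      reactions = "r1", stoichiometry = list(r1 = c(A = 1)),
      lower_bound = c(r1 = 5), upper_bound = c(r1 = 1), objective = "r1"
    ),
    regexp = "r1"
  )
  expect_error(
    metabolic_network(
      reactions = "r1", stoichiometry = list(r1 = c(A = 1)), objective = "nope"
    ),
    class = "network_no_objective"
  )
})

test_that("GPR parsing follows the grammar with and-over-or precedence", {
  g <- parse_gpr("(g1 and g2) or g3")
  expect_equal(g$type, "or")
  expect_equal(g$args[[1]]$type, "and")
  expect_equal(g$args[[2]]$gene, "g3")

  # and binds tighter than or
  g2 <- parse_gpr("a and b or c and d")
  expect_equal(g2$type, "or")
  expect_equal(vapply(g2$args, `[[`, "", "type"), c("and", "and"))

  expect_null(parse_gpr(""))
  expect_null(parse_gpr("   "))
  expect_equal(parse_gpr("G1"), list(type = "gene", gene = "G1"))

  # operators are case-insensitive
  expect_equal(parse_gpr("g1 AND g2"), parse_gpr("g1 and g2"))

  expect_error(parse_gpr("(g1 and g2"), class = "gpr_parse_error")
  expect_error(parse_gpr("g1 and"), class = "gpr_parse_error")
  expect_error(parse_gpr("g1 or or g2"), class = "gpr_parse_error")
  expect_error(parse_gpr("g1 g2)"), regexp = "position")
})

test_that("GPR serialize/parse round-trips random trees", {
  set.seed(42)
  for (i in 1:100) {
    tree <- random_gpr(n_genes = 8, depth = 3)
    expect_equal(parse_gpr(gpr_to_string(tree)), tree)
  }
})

test_that("presence evaluation matches independent expression evaluation", {
  g <- parse_gpr("(g1 and g2) or g3")
  expect_true(evaluate_gpr_presence(g, "g3"))
  expect_false(evaluate_gpr_presence(g, "g1"))
  expect_true(evaluate_gpr_presence(NULL, character()))

  set.seed(7)
  for (i in 1:25) {
    tree <- random_gpr(n_genes = 5, depth = 3)
    genes <- gpr_genes(tree)
    # every subset of the tree's genes
    for (mask in 0:(2^length(genes) - 1)) {
      present <- genes[bitwAnd(mask, 2^(seq_along(genes) - 1)) > 0]
      expect_identical(
        evaluate_gpr_presence(tree, present),
        gpr_presence_by_expression(tree, present)
      )
    }
  }
})

test_that("COBRA-JSON loading reads the toy fixture and flags bad files", {
  path <- system.file("extdata", "toy_model.json", package = "contextflux")
  net <- load_model(path)
  expect_equal(length(net$reactions), 5)
  expect_equal(net$objective, "R_bio")
  expect_equal(net$upper_bound[["EX_glc"]], 5)
  expect_equal(net$subsystem[["HEX1"]], "Glycolysis")
  expect_equal(gpr_to_string(net$gpr$PYK), "(pyk1 and pyk2) or pyk3")

  # bounds inversion is rejected with the reaction named
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$reactions[[2]]$lower_bound <- 50
  doc$reactions[[2]]$upper_bound <- -50
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, bad, auto_unbox = TRUE)
  expect_error(load_model(bad), regexp = "HEX1")

  # no objective
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (i in seq_along(doc$reactions)) doc$reactions[[i]]$objective_coefficient <- 0
  noobj <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, noobj, auto_unbox = TRUE)
  expect_error(load_model(noobj), class = "network_no_objective")

  # malformed json
  txt <- tempfile(fileext = ".json")
  writeLines("{not json", txt)
  expect_error(load_model(txt), class = "model_parse_error")
})

test_that("write/load round-trip preserves random networks exactly", {
  set.seed(11)
  for (i in 1:20) {
    net <- random_oracle_network(i)
    # decorate with random GPRs and subsystems to round-trip those too
    for (r in sample(net$reactions, 3)) {
      net$gpr[[r]] <- random_gpr(n_genes = 5, depth = 2)
      net$subsystem[[r]] <- sample(c("S1", "S2"), 1)
    }
    path <- tempfile(fileext = ".json")
    write_model(net, path)
    back <- load_model(path)
    expect_equal(back$reactions, net$reactions)
    expect_equal(back$stoichiometry, net$stoichiometry)
    expect_equal(back$lower_bound, net$lower_bound)
    expect_equal(back$upper_bound, net$upper_bound)
    expect_equal(back$subsystem, net$subsystem)
    expect_equal(back$gpr, net$gpr)
    expect_equal(back$objective, net$objective)
  }
})

test_that("SBML L3/FBC reading agrees with the COBRA-JSON twin", {
  json_net <- load_model(system.file("extdata", "toy_model.json",
                                     package = "contextflux"))
  sbml_net <- load_model(system.file("extdata", "toy_model_sbml.xml",
                                     package = "contextflux"), format = "sbml")
  expect_setequal(sbml_net$reactions, json_net$reactions)
  expect_equal(sbml_net$objective, "R_bio")
  for (r in json_net$reactions) {
    expect_equal(sort(names(sbml_net$stoichiometry[[r]])),
                 sort(names(json_net$stoichiometry[[r]])))
    expect_equal(sbml_net$stoichiometry[[r]][names(json_net$stoichiometry[[r]])],
                 json_net$stoichiometry[[r]])
    expect_equal(sbml_net$lower_bound[[r]], json_net$lower_bound[[r]])
    expect_equal(sbml_net$upper_bound[[r]], json_net$upper_bound[[r]])
    expect_equal(sbml_net$gpr[[r]], json_net$gpr[[r]])
  }
})

test_that("remove_reactions drops orphans and protects the objective", {
  net <- t1_network()
  red <- remove_reactions(net, "R2")
  expect_setequal(red$reactions, c("EX_A", "R1", "R_bio"))
  expect_equal(red$stoichiometry$R1, net$stoichiometry$R1)
  expect_equal(red$lower_bound[red$reactions], net$lower_bound[red$reactions])

  expect_equal(remove_reactions(net, character())[c("reactions", "stoichiometry")],
               net[c("reactions", "stoichiometry")])

  # removing every reaction touching B drops B
  net2 <- metabolic_network(
    reactions = c("u", "r", "obj"),
    stoichiometry = list(u = c(A = 1), r = c(A = -1, B = 1), obj = c(A = -1)),
    lower_bound = c(u = 0, r = 0, obj = 0),
    upper_bound = c(u = 10, r = 10, obj = 10), objective = "obj"
  )
  red3 <- remove_reactions(net2, "r")
  expect_false("B" %in% red3$metabolites)

  expect_error(remove_reactions(net, "R_bio"), class = "objective_removed")
  expect_error(remove_reactions(net, "nope"), class = "unknown_reaction")
})
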