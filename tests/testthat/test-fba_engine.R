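test_that("FBA on the toy network is forced to the uptake bound", {
  net <- t1_network()
  sol <- fba(net)
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  expect_equal(unname(sol$flux["EX_A"]), 10, tolerance = 1e-9)
  # mass balance of the returned distribution
  expect_lt(max(abs(stoich_matrix(net) %*% sol$flux)), 1e-6)
})

test_that("infeasible and invalid inputs raise typed errors", {
  # a forced producer with no consumer
  net <- metabolic_network(
    reactions = c("make", "obj"),
    stoichiometry = list(make = c(X = 1), obj = c(Y = -1, X = 0.0001)),
    lower_bound = c(make = 5, obj = 0),
    upper_bound = c(make = 10, obj = 0), objective = "obj"
  )
  expect_error(fba(net), class = "lp_infeasible")

  expect_error(lp_settings(feasibility_tolerance = 0), class = "bad_settings")
  expect_error(lp_settings(mass_balance_tolerance = 0.1), class = "bad_settings")
  expect_error(weighted_pfba(t1_network(), fraction = 0), class = "bad_fraction")
  expect_error(weighted_pfba(t1_network(), fraction = 1.2), class = "bad_fraction")
})

test_that("FBA matches the vertex-enumeration oracle on random networks", {
  for (s in 1:30) {
    net <- random_oracle_network(s)
    z_oracle <- oracle_lp_max(net, stats::setNames(1, net$objective))
    z <- fba(net)$objective_value
    expect_equal(z, z_oracle, tolerance = 1e-6)
  }
})

test_that("FVA brackets the attainable flux range", {
  net <- t1_network()
  con <- flux_constraint(coef = c(R_bio = 1), dir = ">=", rhs = 10)
  rng <- fva(net, list(con), c("R1", "R2"))
  expect_equal(unname(rng["R1", ]), c(0, 10), tolerance = 1e-8)
  expect_equal(unname(rng["R2", ]), c(0, 10), tolerance = 1e-8)

  # a reaction fixed by its bounds reports a point range
  net2 <- metabolic_network(
    reactions = c("u", "r", "obj"),
    stoichiometry = list(u = c(A = 1), r = c(A = -1, B = 1), obj = c(B = -1)),
    lower_bound = c(u = 2, r = 0, obj = 0),
    upper_bound = c(u = 2, r = 10, obj = 10), objective = "obj"
  )
  rng2 <- fva(net2, reactions = "u")
  expect_equal(unname(rng2["u", ]), c(2, 2), tolerance = 1e-9)

  # FVA bounds contain feasible points (the pFBA vertex)
  pf <- weighted_pfba(net, NULL)
  rng3 <- fva(net)
  for (r in net$reactions) {
    expect_gte(pf$flux$flux[[r]], rng3[r, "min"] - 1e-8)
    expect_lte(pf$flux$flux[[r]], rng3[r, "max"] + 1e-8)
  }
})

test_that("weighted pFBA routes flux through the cheap pathway", {
  net <- t1_network()
  w <- c(EX_A = 0.5, R1 = 0.1, R2 = 0.9, R_bio = 0.5)
  pf <- weighted_pfba(net, w, fraction = 1)
  v <- pf$flux$flux
  expect_equal(unname(v[c("EX_A", "R1", "R2", "R_bio")]), c(10, 10, 0, 10),
               tolerance = 1e-8)
  # 0.5*10 + 0.1*10 + 0.9*0 + 0.5*10 = 11
  expect_equal(pf$parsimony_value, 11, tolerance = 1e-8)
  # fraction = 1 pins the objective at Z
  expect_equal(unname(v["R_bio"]), pf$fba_objective, tolerance = 1e-8)

  # equal weights: any split v_R1 + v_R2 = 10 is optimal (degenerate tie);
  # the total routed flux is still forced
  pf2 <- weighted_pfba(net, c(EX_A = 0.5, R1 = 0.5, R2 = 0.5, R_bio = 0.5))
  expect_equal(unname(pf2$flux$flux["R1"] + pf2$flux$flux["R2"]), 10,
               tolerance = 1e-8)
  expect_equal(pf2$parsimony_value, 15, tolerance = 1e-8)
})

test_that("unit-weight pFBA equals brute-force total-flux minimization", {
  tested <- 0
  s <- 0
  while (tested < 12 && s < 200) {
    s <- s + 1
    net <- random_oracle_network(2000 + s, n_max = 8)
    Z <- fba(net)$objective_value
    if (Z <= 1e-6) next
    tested <- tested + 1
    pf <- weighted_pfba(net, NULL, fraction = 1)
    w1 <- stats::setNames(rep(1, length(net$reactions)), net$reactions)
    p_oracle <- oracle_min_weighted_l1(net, w1, 1, Z)
    expect_equal(pf$parsimony_value, p_oracle, tolerance = 1e-6)
  }
  expect_gte(tested, 5)
})

test_that("relaxing the objective fraction never increases the parsimony value", {
  net <- t1_network()
  w <- c(EX_A = 0.3, R1 = 0.2, R2 = 0.7, R_bio = 0.4)
  vals <- vapply(c(0.6, 0.8, 1.0), function(f) {
    weighted_pfba(net, w, fraction = f)$parsimony_value
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-9))
})

test_that("returned flux distributions satisfy bounds and mass balance", {
  for (s in c(31:40)) {
    net <- random_oracle_network(s)
    sol <- fba(net)
    expect_true(all(sol$flux >= net$lower_bound - 1e-8))
    expect_true(all(sol$flux <= net$upper_bound + 1e-8))
    expect_lt(max(abs(stoich_matrix(net) %*% sol$flux)), 1e-6)
  }
})
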