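test_that("FBA reproduces hand-computed LP optima on the micro nets", {
  for (net in micro_nets()) {
    sol <- fba(net$model)
    expect_equal(sol$status, "optimal", label = net$model$id)
    expect_equal(sol$objective_value, net$mu, tolerance = 1e-6,
                 label = net$model$id)
    # steady state and bounds of the returned flux vector
    resid <- as.numeric(net$model$S %*% sol$fluxes)
    expect_lt(max(abs(resid)), 1e-6)
    expect_true(all(sol$fluxes >= net$model$reactions$lower_bound - 1e-9))
    expect_true(all(sol$fluxes <= net$model$reactions$upper_bound + 1e-9))
  }
})

test_that("the toy model's rich-medium optimum equals its planted value", {
  tm <- toy_fixture()
  sol <- fba(tm$model)
  expect_equal(sol$objective_value, tm$truth$mu_rich, tolerance = 1e-9)
  expect_equal(tm$truth$mu_rich, 280 / 51)  # closed-form cross-check
  resid <- as.numeric(tm$model$S %*% sol$fluxes)
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("closing every uptake gives zero growth; impossible demands are
          reported infeasible", {
  m <- toy_fixture()$model
  ex <- m$reactions$kind == "exchange"
  m$reactions$lower_bound[ex] <- 0
  expect_equal(fba(m)$objective_value, 0, tolerance = 1e-9)
  m2 <- set_bounds(m, "BIO_replete", lb = 1)  # demand growth with no food
  expect_equal(fba(m2)$status, "infeasible")
})

test_that("FVA envelopes contain the FBA flux and never widen as the
          optimum fraction rises", {
  net <- micro_nets()$diamond
  sol <- fba(net$model)
  prev <- NULL
  for (f in c(0, 0.5, 0.9, 1)) {
    rng <- fva(net$model, fraction_of_optimum = f)
    expect_true(all(rng$min <= rng$max + 1e-9))
    expect_true(all(sol$fluxes[rng$reaction] >= rng$min - 1e-5))
    expect_true(all(sol$fluxes[rng$reaction] <= rng$max + 1e-5))
    if (!is.null(prev)) {
      expect_true(all(rng$min >= prev$min - 1e-6))
      expect_true(all(rng$max <= prev$max + 1e-6))
    }
    prev <- rng
  }
  # parallel unit branches at full optimum: either branch can carry 0..5
  full <- fva(net$model, fraction_of_optimum = 1)
  for (r in c("R1", "R2")) {
    expect_equal(full$min[full$reaction == r], 0, tolerance = 1e-6)
    expect_equal(full$max[full$reaction == r], 5, tolerance = 1e-6)
  }
})

test_that("a closed reaction has FVA range (0, 0)", {
  net <- micro_nets()$split
  m <- set_bounds(net$model, "R2", lb = 0, ub = 0)
  rng <- fva(m, fraction_of_optimum = 0, reactions = "R2")
  expect_equal(c(rng$min, rng$max), c(0, 0))
})

test_that("blocked reactions are exactly the planted orphan branch", {
  tm <- make_toy_model(toy_spec(orphan_branch = TRUE))
  blk <- blocked_reactions(tm$model)
  expect_setequal(blk, c("ORPH1", "ORPH2", "ORPH3"))
  # removing blocked reactions leaves the optimum unchanged
  m2 <- knockout_reactions(tm$model, blk)
  expect_equal(fba(m2)$objective_value, fba(tm$model)$objective_value,
               tolerance = 1e-9)
  # the default toy has no blocked reactions
  expect_length(blocked_reactions(toy_fixture()$model), 0)
})

test_that("a dead-end metabolite's only reaction is blocked", {
  m <- micro_model("dead", list(
    EX_A = rx(c(A_e = -1), lb = -5),
    T_A = rx(c(A_e = -1, A_c = 1)),
    R1 = rx(c(A_c = -1, B_c = 1)),
    DEAD = rx(c(A_c = -1, Z_c = 1)),  # Z has no consumer
    BIO = rx(c(B_c = -1))), "BIO")
  expect_setequal(blocked_reactions(m), "DEAD")
})

test_that("metabolite participation counts are exact on a built case", {
  # cofactor appearing in 7 of 10 reactions tops the ranking
  rxns <- list(EX_A = rx(c(A_e = -1), lb = -5),
               T_A = rx(c(A_e = -1, A_c = 1)))
  for (k in 1:7)
    rxns[[paste0("R", k)]] <- rx(stats::setNames(
      c(-1, 1, -1, 1), c("A_c", paste0("P", k, "_c"), "COF_c", "COFX_c")))
  rxns$BIO <- rx(c(P1_c = -1))
  m <- micro_model("cof", rxns, "BIO")
  conn <- connectivity(m)
  expect_equal(conn$metabolite[1], "A_c")  # substrate feeds all 7 + T_A
  expect_true(all(c("COF_c", "COFX_c") %in% conn$metabolite[1:3]))
  expect_equal(conn$n_reactions[conn$metabolite == "COF_c"], 7)
  expect_equal(conn$n_reactions[conn$metabolite == "P2_c"], 1)
})
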