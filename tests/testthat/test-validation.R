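test_that("growth calls use a strict one-third-of-reference rule and are
          scale invariant", {
  expect_true(growth_call(1, 1)$call)
  expect_false(growth_call(0.30, 1)$call)         # 0.30 < 1/3
  expect_false(growth_call(1 / 3, 1)$call)        # boundary: strictly greater
  expect_true(growth_call(0.34, 1)$call)
  for (c_scale in c(1e-3, 1, 42)) {
    expect_equal(growth_call(0.2 * c_scale, 0.45 * c_scale)$call,
                 growth_call(0.2, 0.45)$call)
  }
  expect_error(growth_call(0.1, 0), "positive")
})

test_that("confusion summaries compute both accuracy definitions", {
  cs <- confusion_summary(TP = 24, TN = 5, FP = 3, FN = 0)
  expect_equal(cs$n, 32)
  expect_equal(cs$accuracy_simple, 29 / 32)
  expect_equal(cs$accuracy_geometric, sqrt(1 * 5 / 8))
  perfect <- confusion_summary(TP = 10, TN = 10, FP = 0, FN = 0)
  expect_equal(perfect$accuracy_simple, 1)
  expect_equal(perfect$accuracy_geometric, 1)
})

test_that("the reference growth rate dominates every constrained condition", {
  tm <- toy_fixture()
  mu_ref <- reference_growth(tm$model)
  expect_equal(mu_ref, tm$truth$mu_rich, tolerance = 1e-9)
  for (tpl in c("autotrophic", "heterotrophic", "dark")) {
    mu <- fba(apply_condition(tm$model, media_condition(tpl, tpl)))$objective_value
    expect_lte(mu, mu_ref + 1e-9)
  }
  # opening uptakes to a common bound is also accepted
  expect_gt(reference_growth(tm$model, uptake_lb = 10), 0)
})

test_that("the planted battery reproduces its confusion counts end to end
          through battery files", {
  tm <- toy_fixture()
  batt <- make_condition_battery(tm$model, tm$truth)
  expect_length(batt, 32)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_battery(batt, path)
  res <- run_battery(tm$model, read_battery(path))
  expect_equal(res$summary$TP, 24)
  expect_equal(res$summary$TN, 5)
  expect_equal(res$summary$FP, 3)
  expect_equal(res$summary$FN, 0)
  expect_equal(res$summary$accuracy_simple, 29 / 32)
  # every in silico call matches the generator's planted expectation
  expect_equal(res$calls$call, attr(batt, "planted_insilico"))
})

test_that("an infeasible condition is counted as no growth, not an error", {
  tm <- toy_fixture()
  # forcing biomass flux while its precursor route is disabled has no
  # feasible steady state at all
  cond <- media_condition("stuck", expected_growth = FALSE,
                          disable_reactions = "GS",
                          exchange_lb = c(BIO_replete = 0.5))
  expect_message(res <- run_battery(tm$model, list(cond)), "no growth")
  expect_equal(res$summary$TN, 1)
  expect_equal(res$calls$mu, 0)
})

test_that("CO2 biofixation and its specific-rate conversion follow the
          mass-fraction formula", {
  expect_equal(co2_specific_uptake(C = 0.5, P = 0)$biofixation, 0)
  out <- co2_specific_uptake(C = 0.5, P = 0.24, X = 1)
  expect_equal(out$biofixation, 0.5 * 0.24 * 44.01 / 12.011,
               tolerance = 1e-12)
  expect_equal(out$biofixation, 0.43971, tolerance = 1e-4)
  # g CO2/L/d over gDW/L and g/mol, to mmol/gDW/h
  expect_equal(out$specific_uptake, out$biofixation / 44.01 * 1000 / 24)
  # averaging rates over samples equals the rate of averages (linearity)
  Ps <- c(0.2, 0.3, 0.4)
  per <- vapply(Ps, function(p)
    co2_specific_uptake(0.5, p, X = 2)$specific_uptake, numeric(1))
  expect_equal(mean(per),
               co2_specific_uptake(0.5, mean(Ps), X = 2)$specific_uptake)
  expect_error(co2_specific_uptake(0.5, 0.1, X = 0), "positive")
})

test_that("growth-rate prediction honours measured uptakes and known
          yields", {
  # one-nutrient net with yield 0.02 gDW per mmol nitrogen
  m <- micro_model("yieldnet", list(
    EX_N = rx(c(N_e = -1), lb = -10),
    T_N = rx(c(N_e = -1, N_c = 1)),
    BIO = rx(c(N_c = -50))), "BIO")
  expect_equal(predict_growth_rate(m, c(EX_N = 1.0)), 0.02,
               tolerance = 1e-9)
  expect_equal(predict_growth_rate(m, c(EX_N = 0)), 0, tolerance = 1e-12)
  expect_error(predict_growth_rate(m, c(EX_missing = 1)), "EX_missing")
  # LP monotonicity: tightening an uptake never increases mu
  tm <- toy_fixture()
  ups <- c(EX_dsa = 5, EX_ac = 10, EX_co2 = 60, EX_photon = 60,
           EX_nh3 = 10, EX_o2 = 10)
  keep <- c("EX_h2o", "EX_h")
  mu1 <- predict_growth_rate(tm$model, ups, keep_open = keep)
  ups2 <- ups; ups2[["EX_dsa"]] <- 2
  mu2 <- predict_growth_rate(tm$model, ups2, keep_open = keep)
  expect_lte(mu2, mu1 + 1e-9)
  ups3 <- ups2; ups3[["EX_nh3"]] <- 4
  expect_lte(predict_growth_rate(tm$model, ups3, keep_open = keep),
             mu2 + 1e-9)
})

test_that("relative growth-rate errors use the experimental denominator", {
  rep0 <- error_report(c(1, 2, 3), c(1, 2, 3))
  expect_equal(rep0$relative_error_pct, c(0, 0, 0))
  rep1 <- error_report(2.0, 1.0)
  expect_equal(rep1$relative_error_pct, 50)
  expect_equal(attr(error_report(c(2, 4), c(1, 5)), "mean_error_pct"),
               mean(c(50, 25)))
  expect_error(error_report(c(1, 0), c(1, 1)), "nonzero")
  expect_error(error_report(1:3, 1:2), "length")
})
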