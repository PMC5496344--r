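test_that("model statistics partition the toy network exactly as generated", {
  tm <- toy_fixture()
  st <- model_stats(tm$model)
  expect_equal(st$n_reactions, 47)
  expect_equal(st$n_metabolites, 36)
  expect_equal(st$n_genes, 15)
  expect_equal(st$n_compartments, 4)
  expect_equal(st$n_exchange, 12)
  expect_equal(st$n_demand, 1)
  expect_equal(st$n_biomass, 2)
  expect_equal(st$n_light, 2)        # photon transport + carboxylation
  expect_equal(st$n_transport, 16)
  # exhaustive, disjoint partition
  expect_equal(st$n_exchange + st$n_demand + st$n_biomass + st$n_light +
                 st$n_transport + st$n_enzymatic, st$n_reactions)
  expect_equal(st$n_gene_associated + st$n_orphan_enzymatic, st$n_enzymatic)
  expect_equal(st$n_orphan_enzymatic, 2)
})

test_that("an empty model yields all-zero statistics", {
  em <- metabolic_model(
    "empty", data.frame(id = "c", name = "cytosol"),
    data.frame(id = character(), name = character(),
               compartment = character(), formula = character(),
               charge = integer()),
    data.frame(id = character(), name = character(),
               lower_bound = numeric(), upper_bound = numeric(),
               subsystem = character(), gpr = character()),
    Matrix::Matrix(0, 0, 0, dimnames = list(character(), character())),
    objective = NA_character_)
  st <- model_stats(em)
  zero_cols <- setdiff(names(st), "n_compartments")
  expect_true(all(st[zero_cols] == 0))
  expect_equal(st$n_compartments, 1)
})

test_that("constructor rejects inconsistent inputs", {
  tm <- toy_fixture()
  m <- tm$model
  bad <- m$reactions
  bad$lower_bound[1] <- bad$upper_bound[1] + 1
  expect_error(
    metabolic_model(m$id, m$compartments, m$metabolites, bad, m$S,
                    objective = m$objective),
    "lower_bound")
  expect_error(
    metabolic_model(m$id, m$compartments, m$metabolites, m$reactions, m$S,
                    objective = "NOT_A_REACTION"),
    "objective")
})

test_that("gene knockouts disable exactly the reactions whose GPR fails", {
  m <- toy_fixture()$model
  # R_A: (g_hk1 and g_pgi) or g_hk2 — isoenzyme survives a partial KO
  k1 <- knockout_genes(m, "g_hk1")
  i <- match("R_A", k1$reactions$id)
  expect_gt(k1$reactions$upper_bound[i], 0)
  k2 <- knockout_genes(m, c("g_hk1", "g_hk2"))
  expect_equal(unname(unlist(
    k2$reactions[match("R_A", k2$reactions$id),
                 c("lower_bound", "upper_bound")])), c(0, 0))
  # reactions without GPR are untouched
  expect_equal(k2$reactions$upper_bound[match("RESP", k2$reactions$id)],
               m$reactions$upper_bound[match("RESP", m$reactions$id)])
  # purity and idempotency
  expect_identical(m$reactions, toy_fixture()$model$reactions)
  expect_identical(knockout_genes(k2, c("g_hk1", "g_hk2"))$reactions,
                   k2$reactions)
  expect_error(knockout_genes(m, "no_such_gene"), "no_such_gene")
})

test_that("knockout of a gene absent from every GPR changes nothing", {
  m <- toy_fixture()$model
  m2 <- m
  m2$genes <- c(m2$genes, "g_unused")
  expect_identical(knockout_genes(m2, "g_unused")$reactions, m2$reactions)
})

test_that("connectivity ranks currency metabolites first", {
  m <- toy_fixture()$model
  conn <- connectivity(m)
  expect_equal(conn$n_reactions,
               sort(conn$n_reactions, decreasing = TRUE))
  # water and the redox carriers participate in many cytosolic reactions
  expect_true(all(c("h2o_c", "redh_c") %in% head(conn$metabolite, 5)))
  one <- conn$n_reactions[conn$metabolite == "aa_c"]
  expect_equal(one, 2)  # synthesis and biomass only
  expect_equal(nrow(connectivity(m, top_k = 3)), 3)
})

test_that("media templates constrain the expected reaction groups", {
  m <- toy_fixture()$model
  # empty condition is the identity
  same <- apply_condition(m, media_condition("null"))
  expect_identical(same$reactions, m$reactions)
  # dark: photon exchange and light reactions shut
  dk <- apply_condition(m, media_condition("dark", "dark"))
  for (r in c("EX_photon", "T_photon", "FIX")) {
    i <- match(r, dk$reactions$id)
    expect_equal(unname(unlist(dk$reactions[i, c("lower_bound",
                                                 "upper_bound")])), c(0, 0))
  }
  # autotrophic: organic carbon closed, O2 uptake capped at 10,
  # light-inhibited enzyme off
  au <- apply_condition(m, media_condition("auto", "autotrophic"))
  expect_equal(au$reactions$lower_bound[match("EX_dsa", au$reactions$id)], 0)
  expect_equal(au$reactions$lower_bound[match("EX_ac", au$reactions$id)], 0)
  expect_equal(au$reactions$lower_bound[match("EX_o2", au$reactions$id)], -10)
  expect_equal(au$reactions$upper_bound[match("OXPHOS2", au$reactions$id)], 0)
  # urea stays open: one carbon atom does not make it an organic C source
  expect_lt(au$reactions$lower_bound[match("EX_urea", au$reactions$id)], 0)
  # idempotent
  au2 <- apply_condition(au, media_condition("auto", "autotrophic"))
  expect_identical(au2$reactions, au$reactions)
  # unknown reference errors
  expect_error(
    apply_condition(m, media_condition("bad", exchange_lb = c(EX_zz = -1))),
    "EX_zz")
})

test_that("battery files round-trip through write_battery/read_battery", {
  tm <- toy_fixture()
  batt <- make_condition_battery(tm$model, tm$truth)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_battery(batt, path)
  back <- read_battery(path)
  expect_equal(length(back), length(batt))
  for (k in seq_along(batt)) {
    expect_equal(back[[k]]$name, batt[[k]]$name)
    expect_equal(back[[k]]$template, batt[[k]]$template)
    expect_equal(back[[k]]$exchange_lb, batt[[k]]$exchange_lb)
    expect_equal(back[[k]]$knockout_genes, batt[[k]]$knockout_genes)
    expect_equal(back[[k]]$expected_growth, batt[[k]]$expected_growth)
  }
})
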