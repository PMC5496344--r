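test_that("SBML round trip preserves the toy model exactly", {
  m <- toy_fixture()$model
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  m2 <- read_sbml(path)
  ix <- match(m2$reactions$id, m$reactions$id)
  expect_false(anyNA(ix))
  expect_equal(nrow(m2$reactions), nrow(m$reactions))
  expect_equal(nrow(m2$metabolites), nrow(m$metabolites))
  expect_setequal(m2$genes, m$genes)
  expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound[ix])
  expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound[ix])
  expect_equal(m2$reactions$gpr, m$reactions$gpr[ix])
  expect_equal(m2$reactions$kind, m$reactions$kind[ix])
  expect_equal(m2$reactions$subsystem, m$reactions$subsystem[ix])
  expect_true(all(abs(m2$S[rownames(m$S), colnames(m$S)] - m$S) < 1e-12))
  mx <- match(m2$metabolites$id, m$metabolites$id)
  expect_equal(m2$metabolites$formula, m$metabolites$formula[mx])
  expect_equal(m2$metabolites$charge, m$metabolites$charge[mx])
  expect_equal(m2$objective, m$objective)
  expect_equal(m2$biomass_variants[names(m$biomass_variants)],
               m$biomass_variants)
  expect_equal(fba(m2)$objective_value, fba(m)$objective_value,
               tolerance = 1e-9)
})

test_that("a written toy file is readable by an independent SBML tool", {
  # cobrapy serves as the external validator/oracle
  m <- toy_fixture()$model
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  main <- reticulate::import_main()
  main$sbml_path <- path
  reticulate::py_run_string(paste0(
    "import cobra\n",
    "cm = cobra.io.read_sbml_model(sbml_path)\n",
    "n_rxn = len(cm.reactions); n_met = len(cm.metabolites)\n",
    "n_gene = len(cm.genes)\n",
    "mu = cm.optimize().objective_value\n"))
  expect_equal(main$n_rxn, nrow(m$reactions))
  expect_equal(main$n_met, nrow(m$metabolites))
  expect_equal(main$n_gene, length(m$genes))
  expect_equal(main$mu, fba(m)$objective_value, tolerance = 1e-6)
})

test_that("an empty model writes a valid minimal document", {
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
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(em, path)
  m2 <- read_sbml(path)
  expect_equal(nrow(m2$reactions), 0)
  expect_equal(nrow(m2$metabolites), 0)
})

test_that("GPR boolean trees survive the fbc geneProductAssociation", {
  m <- micro_model("g", list(
    EX_A = rx(c(A_e = -1), lb = -5),
    T_A = rx(c(A_e = -1, A_c = 1)),
    R1 = rx(c(A_c = -1, B_c = 1)),
    BIO = rx(c(B_c = -1))), "BIO")
  m$reactions$gpr[m$reactions$id == "R1"] <- "(g1 and g2) or g3"
  m$genes <- c("g1", "g2", "g3")
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  m2 <- read_sbml(path)
  expect_equal(m2$reactions$gpr[m2$reactions$id == "R1"],
               "(g1 and g2) or g3")
})

test_that("malformed XML errors and missing bounds default with a warning", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model><unclosed></model>", bad)
  expect_error(read_sbml(bad))

  nb <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="nb">',
    '<listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '<listOfSpecies><species id="A_c" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/></listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="BIO_x" reversible="false" fast="false">',
    '<listOfReactants><speciesReference species="A_c" stoichiometry="1" constant="true"/></listOfReactants>',
    '</reaction>',
    '<reaction id="EX_A" reversible="true" fast="false">',
    '<listOfReactants><speciesReference species="A_c" stoichiometry="1" constant="true"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions>',
    '</model></sbml>'), nb)
  expect_warning(m <- read_sbml(nb), "defaulted")
  expect_equal(m$reactions$lower_bound[m$reactions$id == "EX_A"], -1000)
  expect_equal(m$reactions$lower_bound[m$reactions$id == "BIO_x"], 0)
  expect_equal(m$reactions$upper_bound, c(1000, 1000))
})

test_that("Level 2 kineticLaw bounds and GENE_ASSOCIATION notes are read", {
  l2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="legacy">',
    '<listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="A_c" compartment="c"/>',
    '<species id="B_c" compartment="c"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="R1" reversible="false">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml">',
    '<p>GENE_ASSOCIATION: ga1 or ga2</p></body></notes>',
    '<listOfReactants><speciesReference species="A_c" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B_c" stoichiometry="1"/></listOfProducts>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="0"/>',
    '<parameter id="UPPER_BOUND" value="7.5"/>',
    '</listOfParameters></kineticLaw>',
    '</reaction>',
    '<reaction id="biomass_rxn" reversible="false">',
    '<listOfReactants><speciesReference species="B_c" stoichiometry="1"/></listOfReactants>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="0"/>',
    '<parameter id="UPPER_BOUND" value="1000"/>',
    '</listOfParameters></kineticLaw>',
    '</reaction>',
    '</listOfReactions>',
    '</model></sbml>'), l2)
  m <- read_sbml(l2)
  expect_equal(m$reactions$upper_bound[m$reactions$id == "R1"], 7.5)
  expect_equal(m$reactions$gpr[m$reactions$id == "R1"], "ga1 or ga2")
  expect_equal(m$objective, "biomass_rxn")
})
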