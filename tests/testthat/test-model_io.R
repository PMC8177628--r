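# Model I/O: JSON and SBML-FBC round trips, fixture parsing, toy
# generation determinism.

model_fields <- function(m) {
  list(mets = m$metabolites[order(m$metabolites$id), ],
       rxns = lapply(m$reactions[sort(names(m$reactions))], function(r)
         r[c("id", "stoich", "lb", "ub", "gpr")]),
       genes = sort(m$genes),
       objective = m$objective[sort(names(m$objective))])
}

test_that("JSON round trip is the identity on all downstream fields", {
  m <- make_toy_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  a <- model_fields(m); b <- model_fields(m2)
  rownames(a$mets) <- rownames(b$mets) <- NULL
  expect_equal(b, a)
  # GPR strings survive verbatim
  expect_identical(m2$reactions[["RESP"]]$gpr, "(gResp1 and gResp2)")
  # objective on two reactions is preserved
  m3 <- set_objective(m, c(BIOMASS_A = 1, BIOMASS_B = 0.5))
  write_model(m3, path)
  expect_equal(read_model(path)$objective,
               c(BIOMASS_A = 1, BIOMASS_B = 0.5))
})

test_that("SBML-FBC round trip preserves structure, bounds, GPRs, weights", {
  m <- make_toy_model()
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(m, path)
  m2 <- read_model(path)
  expect_setequal(names(m2$reactions), names(m$reactions))
  expect_setequal(m2$metabolites$id, m$metabolites$id)
  expect_setequal(m2$genes, m$genes)
  expect_equal(reaction_bounds(m2)[names(m$reactions), ],
               reaction_bounds(m))
  for (rid in names(m$reactions)) {
    expect_equal(sort(m2$reactions[[rid]]$stoich),
                 sort(m$reactions[[rid]]$stoich), info = rid)
  }
  expect_equal(m2$metabolites$molecular_weight[
    match(m$metabolites$id, m2$metabolites$id)],
    m$metabolites$molecular_weight)
  expect_equal(m2$objective, m$objective)
  # GPR is equivalent (parenthesisation may differ): same genes, same
  # truth table under single knockouts
  for (rid in c("RESP", "CARBS")) {
    g1 <- m$reactions[[rid]]$gpr; g2 <- m2$reactions[[rid]]$gpr
    expect_setequal(gpr_genes(g2), gpr_genes(g1))
    for (g in gpr_genes(g1))
      expect_equal(evaluate_gpr(g2, g), evaluate_gpr(g1, g), info = rid)
  }
})

test_that("a hand-written SBML fixture parses to its literal contents", {
  fixture <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    ' xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    ' level="3" version="1" fbc:required="false">',
    '<model id="five" fbc:strict="true">',
    '<listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="M_a" name="A" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
    '<species id="M_b" name="B" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
    '</listOfSpecies>',
    '<listOfParameters>',
    '<parameter id="lb1" value="-12.5" constant="true"/>',
    '<parameter id="ub1" value="99" constant="true"/>',
    '<parameter id="zero" value="0" constant="true"/>',
    '</listOfParameters>',
    '<listOfReactions>',
    paste0('<reaction id="R_EX_a" reversible="true" fast="false"',
           ' fbc:lowerFluxBound="lb1" fbc:upperFluxBound="ub1">',
           '<listOfReactants><speciesReference species="M_a" stoichiometry="1" constant="true"/></listOfReactants>',
           '</reaction>'),
    paste0('<reaction id="R_AB" reversible="false" fast="false"',
           ' fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub1">',
           '<listOfReactants><speciesReference species="M_a" stoichiometry="1" constant="true"/></listOfReactants>',
           '<listOfProducts><speciesReference species="M_b" stoichiometry="2" constant="true"/></listOfProducts>',
           '</reaction>'),
    paste0('<reaction id="R_R3" reversible="false" fast="false"',
           ' fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub1">',
           '<listOfReactants><speciesReference species="M_b" stoichiometry="1" constant="true"/></listOfReactants>',
           '</reaction>'),
    paste0('<reaction id="R_R4" reversible="false" fast="false"',
           ' fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub1">',
           '<listOfProducts><speciesReference species="M_a" stoichiometry="1" constant="true"/></listOfProducts>',
           '</reaction>'),
    paste0('<reaction id="R_R5" reversible="false" fast="false"',
           ' fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub1">',
           '<listOfProducts><speciesReference species="M_b" stoichiometry="1" constant="true"/></listOfProducts>',
           '</reaction>'),
    '</listOfReactions>',
    '</model></sbml>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(fixture, path)
  m <- read_model(path)
  expect_length(m$reactions, 5)
  expect_equal(m$reactions[["EX_a"]]$lb, -12.5)
  expect_equal(m$reactions[["EX_a"]]$ub, 99)
  expect_equal(m$reactions[["AB"]]$stoich, c(a = -1, b = 2))
  expect_equal(m$reactions[["AB"]]$lb, 0)
})

test_that("I/O errors are informative", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("<not-sbml/>", path)
  expect_error(read_model(path), "no <model>")
  # missing FBC bounds
  bad <- c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    ' xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    ' level="3" version="1" fbc:required="false">',
    '<model id="x"><listOfSpecies>',
    '<species id="M_a" compartment="c"/></listOfSpecies>',
    '<listOfReactions><reaction id="R_r1" reversible="false">',
    '<listOfReactants><speciesReference species="M_a" stoichiometry="1"/></listOfReactants>',
    '</reaction></listOfReactions></model></sbml>')
  writeLines(bad, path)
  expect_error(read_model(path), "missing FBC flux bounds")
  expect_error(read_model("/nonexistent/model.xml"), "no such file")
})

test_that("make_toy_model is deterministic and always admits v = 0", {
  s <- toy_spec(jitter = 0.05)
  m1 <- make_toy_model(s, seed = 42)
  m2 <- make_toy_model(s, seed = 42)
  expect_identical(model_fields(m1), model_fields(m2))
  m3 <- make_toy_model(s, seed = 43)
  expect_false(identical(
    toy_compositions(m1)$A$entries$coefficient,
    toy_compositions(m3)$A$entries$coefficient))

  # closed state: v = 0 must satisfy every bound, so the all-closed model
  # is feasible with objective 0
  m <- make_toy_model()
  for (ex in exchange_reactions(m))
    m <- set_reaction_bounds(m, ex, lb = 0, ub = 0)
  sol <- solve_fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
})

test_that("zero carbon capacity is a valid, non-growing model", {
  m <- make_toy_model(toy_spec(glc_capacity = 0))
  sol <- solve_fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 0, tolerance = 1e-8)
})

test_that("the chain model reproduces its analytic optimum", {
  m <- make_toy_model(toy_spec(type = "chain", chain_uptake = 10,
                               chain_yield = 0.5))
  expect_equal(solve_fba(m)$objective_value, 5, tolerance = 1e-9)
  m2 <- make_toy_model(toy_spec(type = "chain", chain_uptake = 8,
                                chain_yield = 0.25))
  expect_equal(solve_fba(m2)$objective_value, 2, tolerance = 1e-9)
})
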