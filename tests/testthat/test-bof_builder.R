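# Biomass composition construction, merging, scaling and normalisation.

two_compound_bof <- function(p = 4, l = 0.5, label = "toy2") {
  biomass_composition(data.frame(
    compound = c("prot_c", "lip_c"),
    coefficient = c(p, l),
    side = "consumed",
    group = c("Protein", "Lipid"),
    molecular_weight = c(110, 700)), label = label)
}

test_that("mean_bofs is idempotent, commutative, union-with-zero", {
  b <- two_compound_bof()
  expect_equal(mean_bofs(b, b)$entries, b$entries)

  extra <- biomass_composition(data.frame(
    compound = c("prot_c", "carb_c"),
    coefficient = c(2, 0.4),
    side = "consumed",
    group = c("Protein", "Carbohydrates"),
    molecular_weight = c(110, 162.141)), label = "x")
  m1 <- mean_bofs(b, extra)
  m2 <- mean_bofs(extra, b)
  expect_setequal(m1$entries$compound, c("prot_c", "lip_c", "carb_c"))
  expect_equal(m1$entries[order(m1$entries$compound), -1],
               m2$entries[order(m2$entries$compound), -1],
               ignore_attr = TRUE)
  # compound only in one input is halved
  expect_equal(m1$entries$coefficient[m1$entries$compound == "carb_c"], 0.2)
  expect_equal(m1$entries$coefficient[m1$entries$compound == "lip_c"], 0.25)
  expect_equal(m1$entries$coefficient[m1$entries$compound == "prot_c"], 3)

  conflicted <- biomass_composition(data.frame(
    compound = "prot_c", coefficient = 1, side = "produced",
    group = "Protein", molecular_weight = 110), label = "bad")
  expect_error(mean_bofs(b, conflicted), "side conflict")
})

test_that("remove_compound deletes exactly one entry and its mass", {
  b <- two_compound_bof()
  m0 <- bof_mass(b)
  b2 <- remove_compound(b, "lip_c")
  expect_setequal(b2$entries$compound, "prot_c")
  expect_equal(m0 - bof_mass(b2), 0.5 * 700 / 1000, tolerance = 1e-12)
  expect_error(remove_compound(b, "ghost_c"), "ghost_c")
})

test_that("bof_mass: arithmetic, empty sum, homogeneity", {
  one <- biomass_composition(data.frame(
    compound = "x_c", coefficient = 5, side = "consumed", group = "Others",
    molecular_weight = 200), label = "one")
  expect_equal(bof_mass(one), 1)

  produced_only <- biomass_composition(data.frame(
    compound = "adp_c", coefficient = 3, side = "produced",
    group = "Energy", molecular_weight = 427), label = "p")
  expect_equal(bof_mass(produced_only), 0)

  b <- two_compound_bof()
  b2 <- b; b2$entries$coefficient <- 2 * b2$entries$coefficient
  expect_equal(bof_mass(b2), 2 * bof_mass(b), tolerance = 1e-12)

  # exclusion switch drops the named compounds from the sum
  expect_equal(bof_mass(b, exclude_compounds = "lip_c"),
               4 * 110 / 1000, tolerance = 1e-12)
})

test_that("normalize_unit_mass yields mass 1 and is idempotent", {
  b <- normalize_unit_mass(two_compound_bof())
  expect_equal(bof_mass(b), 1, tolerance = 1e-9)
  b2 <- normalize_unit_mass(b)
  expect_equal(b2$entries$coefficient, b$entries$coefficient,
               tolerance = 1e-12)
  # single-compound fixed point: alpha = 1000/MW
  one <- biomass_composition(data.frame(
    compound = "g_c", coefficient = 10, side = "consumed",
    group = "Carbohydrates", molecular_weight = 180), label = "g")
  expect_equal(normalize_unit_mass(one)$entries$coefficient, 1000 / 180,
               tolerance = 1e-9)
  produced_only <- biomass_composition(data.frame(
    compound = "adp_c", coefficient = 3, side = "produced",
    group = "Energy", molecular_weight = 427), label = "p")
  expect_error(normalize_unit_mass(produced_only), "zero consumed mass")
})

test_that("scale_groups matches hand arithmetic and preserves compounds", {
  b <- two_compound_bof(p = 4, l = 0.5)
  tab <- default_scaling_table()
  nl <- scale_groups(b, tab, "NL")
  # hand oracle: protein x 0.2, lipid x 20, then unit-mass renormalise
  p_raw <- 4 * 0.2; l_raw <- 0.5 * 20
  mass <- (p_raw * 110 + l_raw * 700) / 1000
  expect_equal(nl$entries$coefficient[nl$entries$compound == "prot_c"],
               p_raw / mass, tolerance = 1e-9)
  expect_equal(nl$entries$coefficient[nl$entries$compound == "lip_c"],
               l_raw / mass, tolerance = 1e-9)
  expect_setequal(nl$entries$compound, b$entries$compound)
  expect_equal(bof_mass(nl), 1, tolerance = 1e-9)

  # all-ones column equals plain normalisation
  ul <- scale_groups(b, tab, "UL")
  expect_equal(ul$entries$coefficient,
               normalize_unit_mass(b)$entries$coefficient,
               tolerance = 1e-12)
  expect_error(scale_groups(b, tab, "XX"), "unknown environment")
})

test_that("build_artificial_bofs runs the full pipeline on the toy model", {
  m <- make_toy_model()
  groups <- c(prot_c = "Protein", carb_c = "Carbohydrates",
              lip_c = "Lipid", atp_c = "Energy")
  # identity scaling -> UL = NL = CL
  ident <- scaling_table(matrix(1, 9, 3, dimnames = list(
    c("DNA", "RNA", "Protein", "Lipid", "Carbohydrates", "Energy",
      "Co-factors", "Ions", "Others"), c("UL", "NL", "CL"))))
  out <- build_artificial_bofs(m, ident,
                               source_rxns = c("BIOMASS_A", "BIOMASS_B"),
                               groups = groups)
  expect_equal(out$NL$entries$coefficient, out$UL$entries$coefficient,
               tolerance = 1e-12)
  expect_equal(out$CL$entries$coefficient, out$UL$entries$coefficient,
               tolerance = 1e-12)
  for (b in out) expect_equal(bof_mass(b), 1, tolerance = 1e-9)

  # real table: group mass fractions shift by the scaling ratios
  out2 <- build_artificial_bofs(m, default_scaling_table(),
                                source_rxns = c("BIOMASS_A", "BIOMASS_B"),
                                groups = groups)
  fr_ul <- group_mass_fractions(out2$UL)
  fr_cl <- group_mass_fractions(out2$CL)
  # hand oracle: CL carb fraction = 0.2 f_c / (sum of scaled fractions)
  f <- fr_ul[c("Protein", "Lipid", "Carbohydrates", "Energy")]
  sc <- c(Protein = 3.5, Lipid = 0.26, Carbohydrates = 0.2, Energy = 0.5)
  expect_equal(unname(fr_cl["Carbohydrates"]),
               unname(0.2 * f["Carbohydrates"] / sum(sc * f)),
               tolerance = 1e-9)

  # drop pipeline removes the compound before normalisation
  out3 <- build_artificial_bofs(m, ident, drop = "lip_c",
                                source_rxns = c("BIOMASS_A", "BIOMASS_B"),
                                groups = groups)
  expect_false("lip_c" %in% out3$UL$entries$compound)
  expect_equal(bof_mass(out3$UL), 1, tolerance = 1e-9)
  expect_error(build_artificial_bofs(m, ident, source_rxns =
                                       c("BIOMASS_A", "NOPE"),
                                     groups = groups), "NOPE")
})

test_that("composition TSV round trip preserves entries and environment", {
  b <- normalize_unit_mass(two_compound_bof())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bof(b, path, environment = c(EX_glc_e = 18, EX_nh4_e = 8.5))
  b2 <- read_bof(path)
  expect_equal(b2$entries, b$entries, tolerance = 1e-12)
  expect_equal(b2$label, b$label)
  expect_equal(attr(b2, "environment"),
               c(EX_glc_e = 18, EX_nh4_e = 8.5))
})
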