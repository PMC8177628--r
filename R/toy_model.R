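# Deterministic toy fixtures: a small aerobic heterotroph with glucose and
# ammonium uptake, respiration vs acetate overflow, three macromolecule
# pools (protein, carbohydrate, lipid) and two biomass compositions that
# differ in group make-up.  Small enough that every LP optimum can be
# checked by hand, yet rich enough to exhibit overflow metabolism, RQ
# shifts and nitrogen wasting.

#' Toy model specification
#'
#' @param type `"core"` (default: glucose/ammonium/O2 network with two
#'   biomass compositions) or `"chain"` (a 3-reaction linear chain with an
#'   analytically known optimum: uptake bound `chain_uptake`, yield
#'   `chain_yield`, optimum `chain_uptake * chain_yield`)
#' @param glc_capacity,nh4_capacity,o2_capacity default exchange capacities
#'   (uptake magnitudes, mmol gCDW^-1 h^-1)
#' @param atp_per_glc_resp ATP yield of full glucose oxidation
#' @param atp_per_glc_ferm ATP yield of the acetate-overflow branch
#' @param bof_a,bof_b consumed-side coefficient sets for the two biomass
#'   templates, named vectors over `prot_c`, `carb_c`, `lip_c`, `atp_c`
#'   (mmol per gCDW before unit-mass normalisation)
#' @param jitter lognormal sd applied to BOF coefficients (0 = none); the
#'   `seed` argument of [make_toy_model()] drives this perturbation
#' @return list of class `toy_spec`
#' @export
toy_spec <- function(type = c("core", "chain"),
                     glc_capacity = 10, nh4_capacity = 10,
                     o2_capacity = 1000,
                     atp_per_glc_resp = 26, atp_per_glc_ferm = 2,
                     bof_a = c(prot_c = 6, carb_c = 1, lip_c = 0.2,
                               atp_c = 2),
                     bof_b = c(prot_c = 1.5, carb_c = 5, lip_c = 0.3,
                               atp_c = 2),
                     jitter = 0,
                     chain_uptake = 10, chain_yield = 0.5) {
  type <- match.arg(type)
  structure(list(type = type, glc_capacity = glc_capacity,
                 nh4_capacity = nh4_capacity, o2_capacity = o2_capacity,
                 atp_per_glc_resp = atp_per_glc_resp,
                 atp_per_glc_ferm = atp_per_glc_ferm,
                 bof_a = bof_a, bof_b = bof_b, jitter = jitter,
                 chain_uptake = chain_uptake, chain_yield = chain_yield),
            class = "toy_spec")
}

TOY_GROUPS <- c(prot_c = "Protein", carb_c = "Carbohydrates",
                lip_c = "Lipid", atp_c = "Energy")

TOY_WEIGHTS <- c(glc = 180.156, nh4 = 18.039, o2 = 31.998, co2 = 44.009,
                 ac = 60.052, ala = 89.094, atp = 507.181, prot = 110.0,
                 carb = 162.141, lip = 700.0, s = 100.0)

#' Generate a deterministic toy metabolic model
#'
#' The core model has exchanges for glucose, ammonium, O2, CO2 and acetate,
#' a respiration reaction (glc + 6 O2 -> 6 CO2 + ATP), an overflow branch
#' (glc -> 2 ac + 2 CO2 + ATP), three biosynthesis reactions gated by GPRs,
#' and two unit-mass biomass compositions attached as reactions `BIOMASS_A`
#' (protein-rich) and `BIOMASS_B` (carbohydrate-rich).  The compositions
#' are retrievable with [toy_compositions()].
#'
#' @param spec a [toy_spec()]
#' @param seed integer seed; only consumed when `spec$jitter > 0`, but part
#'   of the determinism contract either way
#' @return a [metabolic_model()] with default objective on `BIOMASS_A`
#' @export
make_toy_model <- function(spec = toy_spec(), seed = 1L) {
  stopifnot(inherits(spec, "toy_spec"))
  if (spec$type == "chain") return(make_chain_model(spec))

  jit <- function(x) {
    if (spec$jitter <= 0) return(x)
    x * exp(stats::rnorm(length(x), 0, spec$jitter))
  }
  if (spec$jitter > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }

  mk_met <- function(base, comp) {
    data.frame(id = paste0(base, "_", comp), name = toupper(base),
               compartment = comp, molecular_weight = TOY_WEIGHTS[[base]],
               formula = NA_character_, stringsAsFactors = FALSE)
  }
  mets <- do.call(rbind, c(
    lapply(c("glc", "nh4", "o2", "co2", "ac", "ala"), function(b)
      rbind(mk_met(b, "e"), mk_met(b, "c"))),
    list(mk_met("atp", "c"), mk_met("prot", "c"), mk_met("carb", "c"),
         mk_met("lip", "c"))))

  rx <- list(
    reaction("EX_glc_e", c(glc_e = -1), lb = -spec$glc_capacity, ub = 1000),
    reaction("EX_nh4_e", c(nh4_e = -1), lb = -spec$nh4_capacity, ub = 1000),
    reaction("EX_o2_e", c(o2_e = -1), lb = -spec$o2_capacity, ub = 1000),
    reaction("EX_co2_e", c(co2_e = -1), lb = 0, ub = 1000),
    reaction("EX_ac_e", c(ac_e = -1), lb = 0, ub = 1000),
    reaction("EX_ala_e", c(ala_e = -1), lb = 0, ub = 1000),
    reaction("GLCt", c(glc_e = -1, glc_c = 1), lb = 0, ub = 1000,
             gpr = "gGlcT"),
    reaction("NH4t", c(nh4_e = -1, nh4_c = 1), lb = 0, ub = 1000,
             gpr = "gNh4T"),
    reaction("O2t", c(o2_e = -1, o2_c = 1), lb = 0, ub = 1000),
    reaction("CO2t", c(co2_c = -1, co2_e = 1), lb = 0, ub = 1000),
    reaction("ACt", c(ac_c = -1, ac_e = 1), lb = 0, ub = 1000),
    # nitrogen overflow: excess ammonium can leave as secreted alanine,
    # at a carbon cost (0.5 glc = 3 C = one alanine)
    reaction("ALAS", c(glc_c = -0.5, nh4_c = -1, ala_c = 1),
             lb = 0, ub = 1000, gpr = "gAla"),
    reaction("ALAt", c(ala_c = -1, ala_e = 1), lb = 0, ub = 1000),
    reaction("RESP", c(glc_c = -1, o2_c = -6, co2_c = 6,
                       atp_c = spec$atp_per_glc_resp),
             lb = 0, ub = 1000, gpr = "(gResp1 and gResp2)"),
    reaction("FERM", c(glc_c = -1, ac_c = 2, co2_c = 2,
                       atp_c = spec$atp_per_glc_ferm),
             lb = 0, ub = 1000, gpr = "gFerm"),
    # non-growth ATP demand (maintenance); also the sink that lets excess
    # carbon be catabolised under forced uptakes
    reaction("ATPM", c(atp_c = -1), lb = 0, ub = 1000),
    reaction("PROTS", c(glc_c = -1, nh4_c = -4, atp_c = -4, prot_c = 4),
             lb = 0, ub = 1000, gpr = "gProt"),
    reaction("CARBS", c(glc_c = -1, atp_c = -1, carb_c = 1),
             lb = 0, ub = 1000, gpr = "(gCarb1 or gCarb2)"),
    reaction("LIPS", c(glc_c = -2, atp_c = -4, lip_c = 1),
             lb = 0, ub = 1000, gpr = "gLip"))

  genes <- c("gGlcT", "gNh4T", "gResp1", "gResp2", "gFerm", "gProt",
             "gCarb1", "gCarb2", "gLip", "gAla")

  mk_bof <- function(coefs, label) {
    coefs <- jit(coefs)
    entries <- data.frame(
      compound = names(coefs),
      coefficient = unname(coefs),
      side = "consumed",
      group = unname(TOY_GROUPS[names(coefs)]),
      molecular_weight = unname(TOY_WEIGHTS[sub("_c$", "", names(coefs))]),
      stringsAsFactors = FALSE)
    normalize_unit_mass(biomass_composition(entries, label = label))
  }
  bof_a <- mk_bof(spec$bof_a, "A")
  bof_b <- mk_bof(spec$bof_b, "B")

  model <- metabolic_model(mets, rx, genes = genes, id = "toy_core")
  model <- attach_bof(model, bof_a, "BIOMASS_A")
  model <- attach_bof(model, bof_b, "BIOMASS_B")
  model <- set_objective(model, c(BIOMASS_A = 1))
  attr(model, "compositions") <- list(A = bof_a, B = bof_b)
  model
}

#' Biomass compositions bundled with a toy model
#'
#' @param model output of [make_toy_model()]
#' @return named list of [biomass_composition()] objects
#' @export
toy_compositions <- function(model) {
  comp <- attr(model, "compositions")
  if (is.null(comp)) stop("model carries no toy compositions")
  comp
}

make_chain_model <- function(spec) {
  mets <- data.frame(
    id = c("s_e", "s_c"), name = c("S", "S"), compartment = c("e", "c"),
    molecular_weight = TOY_WEIGHTS[["s"]], formula = NA_character_,
    stringsAsFactors = FALSE)
  rx <- list(
    reaction("EX_s_e", c(s_e = -1), lb = -spec$chain_uptake, ub = 1000),
    reaction("St", c(s_e = -1, s_c = 1), lb = 0, ub = 1000, gpr = "gSt"),
    reaction("BIOMASS_CHAIN", c(s_c = -1 / spec$chain_yield),
             lb = 0, ub = 1000))
  metabolic_model(mets, rx, genes = "gSt",
                  objective = c(BIOMASS_CHAIN = 1), id = "toy_chain")
}
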