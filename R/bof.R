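# Biomass compositions: construction, merging, scaling and unit-mass
# normalisation.  A composition is the coefficient table of the biomass
# pseudo-reaction: consumed entries are drained per unit growth flux, and
# the consumed mass is conventionally 1 g per gCDW so that the reaction's
# flux is the specific growth rate in h^-1.

BOF_GROUPS <- c("DNA", "RNA", "Protein", "Lipid", "Carbohydrates",
                "Energy", "Co-factors", "Ions", "Others")

#' Construct a biomass composition
#'
#' @param entries data.frame with columns `compound` (metabolite id),
#'   `coefficient` (>= 0, mmol gCDW^-1; the side carries the sign),
#'   `side` (`"consumed"` or `"produced"`), `group` (one of the nine
#'   macromolecular groups) and `molecular_weight` (g/mol; required for
#'   consumed entries)
#' @param label composition label
#' @return object of class `biomass_composition`
#' @export
biomass_composition <- function(entries, label = "BOF") {
  req <- c("compound", "coefficient", "side", "group", "molecular_weight")
  missing_cols <- setdiff(req, names(entries))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  entries <- as.data.frame(entries)[req]
  if (anyDuplicated(entries$compound))
    stop("duplicate compounds in composition: ",
         paste(unique(entries$compound[duplicated(entries$compound)]),
               collapse = ", "))
  if (any(entries$coefficient < 0))
    stop("coefficients must be >= 0 (the side carries the sign)")
  if (!all(entries$side %in% c("consumed", "produced")))
    stop("side must be 'consumed' or 'produced'")
  bad_group <- setdiff(unique(entries$group), BOF_GROUPS)
  if (length(bad_group))
    stop("unknown groups: ", paste(bad_group, collapse = ", "))
  no_mw <- entries$side == "consumed" & is.na(entries$molecular_weight)
  if (any(no_mw))
    stop("consumed entries lack molecular weights: ",
         paste(entries$compound[no_mw], collapse = ", "))
  rownames(entries) <- NULL
  structure(list(entries = entries, label = label),
            class = "biomass_composition")
}

#' @export
print.biomass_composition <- function(x, ...) {
  cat("<biomass_composition> ", x$label, ": ", nrow(x$entries),
      " compounds, consumed mass ",
      format(bof_mass(x), digits = 6), " g/gCDW\n", sep = "")
  invisible(x)
}

#' Arithmetic mean of two biomass compositions
#'
#' The compound set is the union of the inputs; a compound absent from one
#' composition contributes a zero coefficient (so it is halved in the
#' mean).  Groups, sides and molecular weights are inherited and must agree
#' on shared compounds.
#'
#' @param a,b [biomass_composition()] objects
#' @param label label of the result
#' @return the mean composition
#' @export
mean_bofs <- function(a, b, label = paste0("mean(", a$label, ",", b$label, ")")) {
  ea <- a$entries; eb <- b$entries
  shared <- intersect(ea$compound, eb$compound)
  if (length(shared)) {
    ia <- match(shared, ea$compound); ib <- match(shared, eb$compound)
    side_conflict <- ea$side[ia] != eb$side[ib]
    if (any(side_conflict))
      stop("side conflict on shared compounds: ",
           paste(shared[side_conflict], collapse = ", "))
    group_conflict <- ea$group[ia] != eb$group[ib]
    if (any(group_conflict))
      stop("group conflict on shared compounds: ",
           paste(shared[group_conflict], collapse = ", "))
  }
  all_cmp <- union(ea$compound, eb$compound)
  ia <- match(all_cmp, ea$compound); ib <- match(all_cmp, eb$compound)
  coef_a <- ifelse(is.na(ia), 0, ea$coefficient[ia])
  coef_b <- ifelse(is.na(ib), 0, eb$coefficient[ib])
  pick <- function(col) ifelse(is.na(ia), eb[[col]][ib], ea[[col]][ia])
  mw_a <- ea$molecular_weight[ia]; mw_b <- eb$molecular_weight[ib]
  entries <- data.frame(
    compound = all_cmp,
    coefficient = (coef_a + coef_b) / 2,
    side = pick("side"),
    group = pick("group"),
    molecular_weight = ifelse(!is.na(mw_a), mw_a, mw_b),
    stringsAsFactors = FALSE)
  biomass_composition(entries, label = label)
}

#' Remove a compound from a composition
#'
#' @param bof a [biomass_composition()]
#' @param compound compound id to delete
#' @return composition without the compound
#' @export
remove_compound <- function(bof, compound) {
  idx <- match(compound, bof$entries$compound)
  if (is.na(idx)) stop("compound not in composition: ", compound)
  bof$entries <- bof$entries[-idx, , drop = FALSE]
  rownames(bof$entries) <- NULL
  bof
}

#' Consumed mass of a composition
#'
#' Sum over consumed entries of coefficient (mmol/gCDW) times molecular
#' weight (g/mol) divided by 1000, i.e. grams drained per gCDW per unit
#' flux.  Energy-currency compounds count unless explicitly excluded.
#'
#' @param bof a [biomass_composition()]
#' @param exclude_compounds compound ids left out of the sum (e.g. an
#'   ATP-hydrolysis set, for macromolecule-only normalisation)
#' @return mass in g/gCDW
#' @export
bof_mass <- function(bof, exclude_compounds = character()) {
  e <- bof$entries
  keep <- e$side == "consumed" & !(e$compound %in% exclude_compounds)
  if (!any(keep)) return(0)
  if (anyNA(e$molecular_weight[keep]))
    stop("missing molecular weights for: ",
         paste(e$compound[keep & is.na(e$molecular_weight)], collapse = ", "))
  sum(e$coefficient[keep] * e$molecular_weight[keep]) / 1000
}

#' Scale a composition to unit consumed mass
#'
#' Multiplies every coefficient (both sides, keeping the pseudo-reaction
#' internally balanced) by `1/bof_mass(bof)`, so the consumed mass of the
#' result is 1 g/gCDW within 1e-9.
#'
#' @inheritParams bof_mass
#' @return normalised composition
#' @export
normalize_unit_mass <- function(bof, exclude_compounds = character()) {
  m <- bof_mass(bof, exclude_compounds)
  if (m <= 0) stop("composition has zero consumed mass; cannot normalise")
  bof$entries$coefficient <- bof$entries$coefficient / m
  bof
}

#' Group-wise mass fractions of a composition
#'
#' @param bof a [biomass_composition()]
#' @return named numeric vector, fraction of consumed mass per group
#' @export
group_mass_fractions <- function(bof) {
  e <- bof$entries[bof$entries$side == "consumed", ]
  mass <- e$coefficient * e$molecular_weight / 1000
  out <- as.numeric(tapply(mass, factor(e$group, levels = BOF_GROUPS), sum,
                           default = 0))
  stats::setNames(out / sum(out), BOF_GROUPS)
}

#' Construct a group scaling table
#'
#' One positive factor per macromolecular group and environment column.
#' Environment coordinates (named uptake vectors) may be attached per
#' column; they place each column's composition in nutrient space.
#'
#' @param factors matrix (groups x environments) of positive scalars; all
#'   nine groups must be present as row names
#' @param coordinates optional named list, one uptake-coordinate vector per
#'   environment column
#' @return object of class `scaling_table`
#' @export
scaling_table <- function(factors, coordinates = NULL) {
  factors <- as.matrix(factors)
  if (!setequal(rownames(factors), BOF_GROUPS))
    stop("scaling table must contain exactly the nine groups")
  factors <- factors[BOF_GROUPS, , drop = FALSE]
  if (any(factors <= 0)) stop("all scaling factors must be > 0")
  if (!is.null(coordinates)) {
    bad <- setdiff(names(coordinates), colnames(factors))
    if (length(bad)) stop("coordinates for unknown environments: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(factors = factors, coordinates = coordinates),
            class = "scaling_table")
}

#' Default three-environment scaling table
#'
#' Group scaling factors for an unlimited (UL), nitrogen-limited (NL) and
#' carbon-limited (CL) environment, with the corresponding glucose and
#' ammonium uptake coordinates (mmol gCDW^-1 h^-1): UL (18, 8.5),
#' NL (13.5, 1.5), CL (1.5, 0.68).  Nitrogen limitation shrinks the protein
#' fraction and inflates storage (lipid, carbohydrate); carbon limitation
#' does the opposite.
#'
#' @return a [scaling_table()]
#' @export
default_scaling_table <- function() {
  f <- matrix(
    c(1, 1.1, 1.9,
      1, 0.86, 1.6,
      1, 0.2, 3.5,
      1, 20, 0.26,
      1, 15, 0.2,
      1, 4, 0.5,
      1, 4, 3,
      1, 1, 1.1,
      1, 3, 2),
    nrow = 9, byrow = TRUE,
    dimnames = list(BOF_GROUPS, c("UL", "NL", "CL")))
  scaling_table(f, coordinates = list(
    UL = c(EX_glc_e = 18, EX_nh4_e = 8.5),
    NL = c(EX_glc_e = 13.5, EX_nh4_e = 1.5),
    CL = c(EX_glc_e = 1.5, EX_nh4_e = 0.68)))
}

#' Scale a composition by group factors
#'
#' Each coefficient (both sides) is multiplied by the factor of its group
#' in the chosen environment column; the result is then re-normalised to
#' unit consumed mass.  The compound set is preserved exactly.
#'
#' @param bof a [biomass_composition()]
#' @param table a [scaling_table()]
#' @param environment column label in `table`
#' @return scaled, unit-mass composition
#' @export
scale_groups <- function(bof, table, environment) {
  stopifnot(inherits(table, "scaling_table"))
  if (!environment %in% colnames(table$factors))
    stop("unknown environment column: ", environment)
  fac <- table$factors[, environment]
  unknown <- setdiff(unique(bof$entries$group), names(fac))
  if (length(unknown))
    stop("groups missing from scaling table: ",
         paste(unknown, collapse = ", "))
  bof$entries$coefficient <- bof$entries$coefficient *
    unname(fac[bof$entries$group])
  bof$label <- paste0(bof$label, ":", environment)
  normalize_unit_mass(bof)
}

#' Build artificial UL/NL/CL compositions from a model's source biomasses
#'
#' Pipeline: take the arithmetic mean of the two source biomass reactions,
#' remove the `drop` compounds, normalise to unit mass (this is UL), then
#' scale groups per the NL and CL columns of the table (each re-normalised).
#'
#' @param model a [metabolic_model()] containing the two source reactions
#' @param table a [scaling_table()] with columns `UL`, `NL`, `CL`
#' @param drop compound ids removed after merging (e.g. a compound that
#'   blocks growth in the distributed medium)
#' @param source_rxns ids of the two source biomass reactions
#' @param groups named character vector, compound id -> group, for every
#'   compound in the source reactions
#' @param weights optional named numeric of molecular weights (g/mol) used
#'   where the model metabolite carries none
#' @return named list of three unit-mass compositions: `UL`, `NL`, `CL`
#' @export
build_artificial_bofs <- function(model, table = default_scaling_table(),
                                  drop = character(), source_rxns, groups,
                                  weights = NULL) {
  missing_rxn <- setdiff(source_rxns, names(model$reactions))
  if (length(missing_rxn))
    stop("source biomass reactions not in model: ",
         paste(missing_rxn, collapse = ", "))
  if (length(source_rxns) != 2L)
    stop("exactly two source biomass reactions are required")
  comps <- lapply(source_rxns, function(rid)
    composition_from_reaction(model, rid, groups, weights))
  merged <- mean_bofs(comps[[1]], comps[[2]])
  for (cmp in drop) merged <- remove_compound(merged, cmp)
  ul <- normalize_unit_mass(merged)
  ul$label <- "UL"
  list(UL = ul,
       NL = scale_groups(ul, table, "NL"),
       CL = scale_groups(ul, table, "CL"))
}

#' Extract a biomass composition from a model reaction
#'
#' @param model a [metabolic_model()]
#' @param rxn_id biomass reaction id
#' @param groups named character vector, compound id -> group
#' @param weights optional molecular-weight fallback table
#' @return a [biomass_composition()]
#' @export
composition_from_reaction <- function(model, rxn_id, groups,
                                      weights = NULL) {
  if (!rxn_id %in% names(model$reactions))
    stop("unknown reaction: ", rxn_id)
  st <- model$reactions[[rxn_id]]$stoich
  cmp <- names(st)
  no_group <- setdiff(cmp, names(groups))
  if (length(no_group))
    stop("no group assignment for: ", paste(no_group, collapse = ", "))
  mw <- metabolite_weight(model, cmp)
  if (!is.null(weights)) {
    use <- is.na(mw) & cmp %in% names(weights)
    mw[use] <- weights[cmp[use]]
  }
  entries <- data.frame(
    compound = cmp,
    coefficient = abs(unname(st)),
    side = ifelse(st < 0, "consumed", "produced"),
    group = unname(groups[cmp]),
    molecular_weight = mw,
    stringsAsFactors = FALSE)
  biomass_composition(entries, label = rxn_id)
}

#' Attach a biomass composition to a model as a pseudo-reaction
#'
#' Consumed entries get negative stoichiometry, produced entries positive;
#' the reaction is irreversible with bounds (0, `ub`).
#'
#' @param model a [metabolic_model()]
#' @param bof a [biomass_composition()]
#' @param id id for the new reaction
#' @param ub upper flux bound
#' @return model containing the new reaction
#' @export
attach_bof <- function(model, bof, id, ub = 1000) {
  e <- bof$entries
  missing_cmp <- setdiff(e$compound, model$metabolites$id)
  if (length(missing_cmp))
    stop("BOF compounds absent from model: ",
         paste(missing_cmp, collapse = ", "))
  st <- stats::setNames(ifelse(e$side == "consumed", -1, 1) * e$coefficient,
                        e$compound)
  st <- st[st != 0]
  add_reaction(model, reaction(id, st, lb = 0, ub = ub,
                               name = paste0("Biomass ", bof$label)))
}

# ---- composition tables on disk ---------------------------------------

#' Read / write biomass composition tables
#'
#' TSV with columns `compound_id`, `side`, `coefficient`, `group`,
#' `molecular_weight`; `#`-prefixed header lines carry the label and,
#' optionally, environment coordinates (`# env: EX_glc_e=18 EX_nh4_e=8.5`).
#'
#' @param path file path
#' @return `read_bof`: a [biomass_composition()] (with an `environment`
#'   attribute when coordinates are present)
#' @export
read_bof <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  label <- sub("^#\\s*label:\\s*", "", grep("^#\\s*label:", hdr, value = TRUE))
  envline <- sub("^#\\s*env:\\s*", "", grep("^#\\s*env:", hdr, value = TRUE))
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                           stringsAsFactors = FALSE)
  bof <- biomass_composition(
    data.frame(compound = tab$compound_id, coefficient = tab$coefficient,
               side = tab$side, group = tab$group,
               molecular_weight = tab$molecular_weight,
               stringsAsFactors = FALSE),
    label = if (length(label)) label[1] else "BOF")
  if (length(envline)) {
    kv <- strsplit(strsplit(envline[1], "\\s+")[[1]], "=")
    attr(bof, "environment") <- stats::setNames(
      vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
      vapply(kv, `[[`, character(1), 1))
  }
  bof
}

#' @rdname read_bof
#' @param bof a [biomass_composition()]
#' @param environment optional named uptake-coordinate vector written to
#'   the header
#' @export
write_bof <- function(bof, path, environment = NULL) {
  hdr <- paste0("# label: ", bof$label)
  if (!is.null(environment)) {
    hdr <- c(hdr, paste0("# env: ", paste(names(environment), environment,
                                          sep = "=", collapse = " ")))
  }
  e <- bof$entries
  body <- data.frame(compound_id = e$compound, side = e$side,
                     coefficient = e$coefficient, group = e$group,
                     molecular_weight = e$molecular_weight)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
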