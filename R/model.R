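# Core containers: metabolites, reactions, and the metabolic_model S3 class.
# The representation is deliberately plain (data.frame + list) -- models at
# the scale this package targets do not need sparse storage.

#' Construct a metabolic model
#'
#' A `metabolic_model` bundles metabolites, reactions, genes and a linear
#' objective.  Fluxes are in mmol gCDW^-1 h^-1 (biomass pseudo-reactions:
#' h^-1); uptake through an exchange reaction is a negative flux.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `molecular_weight` (g/mol, NA allowed) and `formula` (NA allowed)
#' @param reactions list of reactions as returned by [reaction()]
#' @param genes character vector of gene identifiers
#' @param objective named numeric vector of objective coefficients keyed by
#'   reaction id
#' @param id model identifier
#' @return object of class `metabolic_model`
#' @export
#' @examples
#' m <- metabolic_model(
#'   metabolites = data.frame(id = "a_c", name = "A", compartment = "c",
#'                            molecular_weight = 100, formula = NA),
#'   reactions = list(reaction("EX_a_e", c(a_c = -1), lb = -10, ub = 1000)),
#'   genes = character(), objective = c(EX_a_e = 1))
metabolic_model <- function(metabolites, reactions, genes = character(),
                            objective = numeric(), id = "model") {
  met_cols <- c("id", "name", "compartment", "molecular_weight", "formula")
  for (col in setdiff(met_cols, names(metabolites))) {
    metabolites[[col]] <- if (col == "molecular_weight") NA_real_ else NA_character_
  }
  metabolites <- metabolites[met_cols]
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  model <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         genes = genes, objective = objective),
    class = "metabolic_model")
  validate_model(model)
  model
}

#' Construct a reaction
#'
#' @param id reaction identifier
#' @param stoich named numeric vector, metabolite id -> signed coefficient
#'   (consumed < 0, produced > 0)
#' @param lb,ub flux bounds, `lb <= ub`
#' @param gpr gene-protein-reaction rule (boolean expression over gene ids
#'   with `and`/`or`/parentheses), or `NA` for none
#' @param name human-readable name
#' @return list with class `mb_reaction`
#' @export
reaction <- function(id, stoich, lb = -1000, ub = 1000, gpr = NA_character_,
                     name = id) {
  if (!length(stoich)) stop("reaction '", id, "': empty stoichiometry")
  if (is.null(names(stoich)) || any(!nzchar(names(stoich))))
    stop("reaction '", id, "': stoichiometry must be a named vector")
  if (lb > ub) stop("reaction '", id, "': lower bound exceeds upper bound")
  structure(list(id = id, name = name, stoich = stoich,
                 lb = as.numeric(lb), ub = as.numeric(ub),
                 gpr = gpr), class = "mb_reaction")
}

validate_model <- function(model) {
  mids <- model$metabolites$id
  if (anyDuplicated(mids)) stop("duplicate metabolite ids")
  rids <- vapply(model$reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids)) stop("duplicate reaction ids")
  for (rxn in model$reactions) {
    missing <- setdiff(names(rxn$stoich), mids)
    if (length(missing))
      stop("reaction '", rxn$id, "' references unknown metabolites: ",
           paste(missing, collapse = ", "))
    if (rxn$lb > rxn$ub)
      stop("reaction '", rxn$id, "': lb > ub")
    if (!is.na(rxn$gpr) && nzchar(rxn$gpr)) {
      gs <- gpr_genes(rxn$gpr)
      unknown <- setdiff(gs, model$genes)
      if (length(unknown))
        stop("reaction '", rxn$id, "' GPR uses genes not in model: ",
             paste(unknown, collapse = ", "))
    }
  }
  bad_obj <- setdiff(names(model$objective), rids)
  if (length(bad_obj))
    stop("objective references unknown reactions: ",
         paste(bad_obj, collapse = ", "))
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$metabolites), "\n",
      "  reactions:   ", length(x$reactions), "\n",
      "  genes:       ", length(x$genes), "\n",
      "  objective:   ",
      if (length(x$objective)) paste(names(x$objective), collapse = ", ")
      else "(none)", "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a [metabolic_model()]
#' @return dense matrix S (metabolites x reactions), dimnames set
#' @export
stoichiometric_matrix <- function(model) {
  mids <- model$metabolites$id
  rids <- names(model$reactions)
  S <- matrix(0, length(mids), length(rids), dimnames = list(mids, rids))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoich
    S[names(st), j] <- st
  }
  S
}

#' Reaction bound accessors
#'
#' `reaction_bounds` returns a two-column matrix of bounds;
#' `set_reaction_bounds` returns a modified model.
#'
#' @param model a [metabolic_model()]
#' @param id reaction id
#' @param lb,ub new bounds (either may be omitted to keep the current value)
#' @return model with updated bounds
#' @export
set_reaction_bounds <- function(model, id, lb = NULL, ub = NULL) {
  if (!id %in% names(model$reactions))
    stop("unknown reaction: ", id)
  if (!is.null(lb)) model$reactions[[id]]$lb <- as.numeric(lb)
  if (!is.null(ub)) model$reactions[[id]]$ub <- as.numeric(ub)
  if (model$reactions[[id]]$lb > model$reactions[[id]]$ub)
    stop("reaction '", id, "': lb > ub after update")
  model
}

#' @rdname set_reaction_bounds
#' @export
reaction_bounds <- function(model) {
  cbind(lb = vapply(model$reactions, `[[`, numeric(1), "lb"),
        ub = vapply(model$reactions, `[[`, numeric(1), "ub"))
}

#' Add a reaction to a model
#'
#' @param model a [metabolic_model()]
#' @param rxn a [reaction()]
#' @return model containing `rxn`
#' @export
add_reaction <- function(model, rxn) {
  if (rxn$id %in% names(model$reactions))
    stop("reaction '", rxn$id, "' already present")
  missing <- setdiff(names(rxn$stoich), model$metabolites$id)
  if (length(missing))
    stop("reaction '", rxn$id, "' references unknown metabolites: ",
         paste(missing, collapse = ", "))
  model$reactions[[rxn$id]] <- rxn
  model
}

#' Exchange reactions of a model
#'
#' Exchanges are boundary reactions with a single metabolite in their
#' stoichiometry (conventionally prefixed `EX_`); uptake is negative flux.
#'
#' @param model a [metabolic_model()]
#' @return character vector of exchange reaction ids
#' @export
exchange_reactions <- function(model) {
  is_ex <- vapply(model$reactions, function(r)
    length(r$stoich) == 1L && startsWith(r$id, "EX_"), logical(1))
  names(model$reactions)[is_ex]
}

#' Set the model objective
#'
#' @param model a [metabolic_model()]
#' @param objective named numeric vector of coefficients keyed by reaction id
#' @return model with replaced objective
#' @export
set_objective <- function(model, objective) {
  bad <- setdiff(names(objective), names(model$reactions))
  if (length(bad)) stop("objective references unknown reactions: ",
                        paste(bad, collapse = ", "))
  model$objective <- objective
  model
}

# Monoisotopic-free average atomic masses for formula-derived weights.
ATOMIC_WEIGHTS <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06, Na = 22.990, K = 39.098,
                    Mg = 24.305, Ca = 40.078, Fe = 55.845, Cl = 35.45,
                    Zn = 65.38, Cu = 63.546, Mn = 54.938, Co = 58.933,
                    Mo = 95.95, Ni = 58.693, Se = 78.971, R = 0)

#' Molecular weight from a chemical formula
#'
#' @param formula e.g. `"C6H12O6"`; charge suffixes are not supported
#' @return weight in g/mol
#' @export
formula_weight <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(NA_real_)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    if (!length(parts) || sum(nchar(parts)) != nchar(f))
      stop("cannot parse formula: ", f)
    w <- 0
    for (p in parts) {
      el <- sub("[0-9]*$", "", p)
      cnt <- sub("^[A-Za-z]+", "", p)
      cnt <- if (nzchar(cnt)) as.numeric(cnt) else 1
      if (!el %in% names(ATOMIC_WEIGHTS))
        stop("unknown element '", el, "' in formula ", f)
      w <- w + ATOMIC_WEIGHTS[[el]] * cnt
    }
    w
  }, numeric(1), USE.NAMES = FALSE)
}

#' Molecular weight of a metabolite in a model
#'
#' Uses the stored `molecular_weight` when present, otherwise derives it
#' from the formula.
#'
#' @param model a [metabolic_model()]
#' @param ids metabolite ids
#' @return numeric vector of weights (g/mol), NA where unknown
#' @export
metabolite_weight <- function(model, ids) {
  idx <- match(ids, model$metabolites$id)
  if (anyNA(idx)) stop("unknown metabolites: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  w <- model$metabolites$molecular_weight[idx]
  need <- is.na(w)
  if (any(need)) {
    w[need] <- suppressWarnings(
      formula_weight(model$metabolites$formula[idx[need]]))
  }
  w
}
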