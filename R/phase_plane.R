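# Phenotype phase planes: grids over two exchange axes (conventionally
# glucose x ammonium) evaluating growth, maximal acetate secretion and the
# respiratory quotient per cell, for any biomass source -- a fixed
# composition, a BTW model, or a HIP map (fresh composition per cell).
# Cells are independent; failures are recorded in the cell status, never
# propagated.

# For the lexicographic stages of a BTW model the *sum* of the BOF fluxes
# must be pinned, not each split.  A pseudo-metabolite produced one-to-one
# by every BTW reaction and drained by BTW_TOTAL turns that sum into an
# ordinary reaction flux.
btw_with_total <- function(model) {
  ids <- attr(model, "btw_reactions")
  model$metabolites <- rbind(model$metabolites, data.frame(
    id = "btw_growth_total", name = "BTW growth total", compartment = "c",
    molecular_weight = NA_real_, formula = NA_character_))
  for (rid in ids)
    model$reactions[[rid]]$stoich <- c(model$reactions[[rid]]$stoich,
                                       btw_growth_total = 1)
  model <- add_reaction(model, reaction("BTW_TOTAL",
                                        c(btw_growth_total = -1),
                                        lb = 0, ub = 1000))
  model
}

# Prepare one grid cell: environment-applied model, its growth reaction,
# and the growth value.  status != "optimal" means no usable solution.
prepare_cell <- function(model, bof_source, env, iterate, eps, k_max, tol) {
  is_btw <- inherits(bof_source, "metabolic_model") &&
    !is.null(attr(bof_source, "btw_reactions"))
  is_map <- inherits(bof_source, "affine_bof_map")

  if (is_btw) {
    m <- apply_environment(btw_with_total(bof_source), env)
    sol <- solve_fba(m, stats::setNames(1, "BTW_TOTAL"), tol = tol)
    return(list(model = m, growth_rxn = "BTW_TOTAL", status = sol$status,
                growth = sol$objective_value))
  }
  if (is_map) {
    if (iterate) {
      res <- hip_i_solve(model, bof_source, env, eps = eps, k_max = k_max,
                         tol = tol)
      if (res$status != "optimal")
        return(list(status = res$status, growth = NA_real_))
      if (!res$converged)
        return(list(status = "not_converged", growth = res$growth))
      final_bof <- res$compositions[[length(res$compositions)]]
      m <- apply_environment(attach_bof(model, final_bof, "BIOMASS_HIP"),
                             env)
      return(list(model = m, growth_rxn = "BIOMASS_HIP",
                  status = "optimal", growth = res$growth))
    }
    bof <- hip_bof(bof_source, env)
    m <- apply_environment(attach_bof(model, bof, "BIOMASS_HIP"), env)
    sol <- solve_fba(m, stats::setNames(1, "BIOMASS_HIP"), tol = tol)
    return(list(model = m, growth_rxn = "BIOMASS_HIP", status = sol$status,
                growth = sol$objective_value))
  }
  # fixed composition
  m <- apply_environment(attach_bof(model, bof_source, "BIOMASS_FIXED"),
                         env)
  sol <- solve_fba(m, stats::setNames(1, "BIOMASS_FIXED"), tol = tol)
  list(model = m, growth_rxn = "BIOMASS_FIXED", status = sol$status,
       growth = sol$objective_value)
}

#' Scan a 2-D phenotype phase plane
#'
#' Each cell is evaluated independently: growth via the source's own solve,
#' maximal acetate via the lexicographic stage, and RQ via the three-level
#' parsimonious procedure.  A HIP source generates a fresh composition per
#' coordinate; with `iterate = TRUE` the HIP-I fixed point is used and
#' non-converged cells are flagged.
#'
#' @param model a [metabolic_model()] (without the biomass source attached)
#' @param bof_source a [biomass_composition()] (fixed biomass), a model
#'   returned by [build_btw()], or an [fit_affine_map()] result
#' @param c_values,n_values uptake magnitudes along the carbon and nitrogen
#'   axes (mmol gCDW^-1 h^-1)
#' @param phenotypes subset of `c("growth", "acetate", "rq")`
#' @param mode `"fixed"` uptakes or `"upper_bound"` (required for HIP-I)
#' @param c_id,n_id exchange reaction ids of the two axes
#' @param acetate_rxn,o2_rxn,co2_rxn exchange ids used by the phenotype
#'   solves
#' @param iterate use HIP-I instead of HIP when `bof_source` is a map
#' @param eps,k_max HIP-I settings (see [hip_i_solve()])
#' @param tol solver tolerance
#' @return object of class `phase_plane_grid`: long-format data.frame in
#'   `$cells` (glc, nh4, growth, acetate, rq, status) plus axis metadata
#'   and a `bof_source` tag
#' @export
scan_phase_plane <- function(model, bof_source, c_values, n_values,
                             phenotypes = c("growth", "acetate", "rq"),
                             mode = c("fixed", "upper_bound"),
                             c_id = "EX_glc_e", n_id = "EX_nh4_e",
                             acetate_rxn = "EX_ac_e", o2_rxn = "EX_o2_e",
                             co2_rxn = "EX_co2_e", iterate = FALSE,
                             eps = 1e-3, k_max = 100, tol = MB_TOL) {
  mode <- match.arg(mode)
  phenotypes <- match.arg(phenotypes, several.ok = TRUE)
  if (!length(c_values) || !length(n_values))
    stop("axis value lists must be non-empty")
  if (any(c_values < 0) || any(n_values < 0))
    stop("axis values must be nonnegative")
  if (iterate && mode != "upper_bound")
    stop("HIP-I scanning requires mode = 'upper_bound'")
  is_btw <- inherits(bof_source, "metabolic_model") &&
    !is.null(attr(bof_source, "btw_reactions"))
  is_map <- inherits(bof_source, "affine_bof_map")
  if (!is_btw && !is_map && !inherits(bof_source, "biomass_composition"))
    stop("unsupported bof_source")
  source_tag <- if (is_btw) "btw" else if (is_map) {
    if (iterate) "hipi" else "hip"
  } else "fixed"

  grid <- expand.grid(glc = c_values, nh4 = n_values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    env <- environment_point(
      stats::setNames(c(grid$glc[i], grid$nh4[i]), c(c_id, n_id)),
      mode = mode)
    cell <- data.frame(glc = grid$glc[i], nh4 = grid$nh4[i],
                       growth = NA_real_, acetate = NA_real_,
                       rq = NA_real_, status = "optimal",
                       stringsAsFactors = FALSE)
    prep <- prepare_cell(model, bof_source, env, iterate, eps, k_max, tol)
    cell$status <- prep$status
    if (!prep$status %in% c("optimal", "not_converged")) return(cell)
    cell$growth <- prep$growth
    if (prep$status == "not_converged") return(cell)
    if (prep$growth <= 10 * tol) {
      cell$status <- "no_growth"
      return(cell)
    }
    if ("acetate" %in% phenotypes) {
      sec <- max_secretion_at_optimal_growth(prep$model, prep$growth_rxn,
                                             acetate_rxn, tol = tol)
      if (sec$status == "optimal") cell$acetate <- sec$objective_value
    }
    if ("rq" %in% phenotypes) {
      cell$rq <- tryCatch(
        respiratory_quotient(prep$model, env = NULL, prep$growth_rxn,
                             acetate_rxn, o2_rxn, co2_rxn, tol = tol),
        multibof_undefined_rq = function(e) NA_real_,
        multibof_infeasible = function(e) NA_real_)
    }
    cell
  })
  structure(list(cells = do.call(rbind, rows),
                 axes = list(c = list(id = c_id, values = c_values),
                             n = list(id = n_id, values = n_values)),
                 bof_source = source_tag, mode = mode),
            class = "phase_plane_grid")
}

#' @export
print.phase_plane_grid <- function(x, ...) {
  cat("<phase_plane_grid> ", x$bof_source, ", ",
      length(x$axes$c$values), " x ", length(x$axes$n$values),
      " cells (", x$axes$c$id, " x ", x$axes$n$id, "), mode ", x$mode,
      "\n", sep = "")
  invisible(x)
}

#' Cell-wise ratio of two phase-plane grids
#'
#' Divides each phenotype column by the reference grid's.  Where the
#' reference is zero and the numerator positive the cell is flagged
#' `undefined_positive` (the ratio column carries NA); 0/0 yields 1 with
#' status `zero_over_zero`.  Acetate ratios are capped at `cap`.
#'
#' @param grid,reference_grid `phase_plane_grid` objects on identical axes
#' @param cap upper cap applied to the acetate ratio (default 10)
#' @return a `phase_plane_grid` of ratios (status column per cell)
#' @export
relative_grid <- function(grid, reference_grid, cap = 10) {
  ax <- function(g) list(g$axes$c$id, g$axes$c$values, g$axes$n$id,
                         g$axes$n$values)
  if (!identical(ax(grid), ax(reference_grid)))
    stop("grids have different axes")
  num <- grid$cells; den <- reference_grid$cells
  out <- num
  ztol <- 1e-12
  for (col in c("growth", "acetate", "rq")) {
    a <- num[[col]]; b <- den[[col]]
    r <- a / b
    both_zero <- !is.na(a) & !is.na(b) & abs(a) <= ztol & abs(b) <= ztol
    undef <- !is.na(a) & !is.na(b) & abs(b) <= ztol & a > ztol
    r[both_zero] <- 1
    r[undef] <- NA_real_
    if (col == "acetate") r <- pmin(r, cap)
    out[[col]] <- r
    out$status[both_zero & out$status == "optimal"] <- "zero_over_zero"
    out$status[undef] <- "undefined_positive"
  }
  bad <- num$status %in% c("infeasible", "not_converged") |
    den$status %in% c("infeasible", "not_converged")
  out$status[bad] <- "no_reference"
  out$growth[bad] <- NA_real_; out$acetate[bad] <- NA_real_
  out$rq[bad] <- NA_real_
  structure(list(cells = out, axes = grid$axes,
                 bof_source = paste0(grid$bof_source, "/",
                                     reference_grid$bof_source),
                 mode = grid$mode),
            class = "phase_plane_grid")
}

#' Export a phase-plane grid as long-format TSV
#'
#' @param grid a `phase_plane_grid`
#' @param path destination
#' @return invisibly, `path`
#' @export
write_grid <- function(grid, path) {
  utils::write.table(grid$cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
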