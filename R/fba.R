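# Linear-programming core: standard FBA, environment application,
# lexicographic secretion maximisation, parsimonious FBA and the
# respiratory quotient.  All solves share the simplex backend in lp.R and
# default to 1e-9 feasibility/optimality tolerances; "fixing at the
# optimum" uses equality bounds widened by a 1e-9 relative slack so that
# round-off cannot make the follow-up stage infeasible.

MB_TOL <- 1e-9

fix_slack <- function(v, tol = MB_TOL) max(1, abs(v)) * tol

#' Define an environment point
#'
#' Uptake magnitudes (nonnegative, mmol gCDW^-1 h^-1) for named exchange
#' reactions, applied either as fixed values or as upper bounds on uptake.
#'
#' @param uptakes named numeric vector, exchange reaction id -> uptake
#'   magnitude
#' @param mode `"fixed"` (exchange flux pinned to -uptake) or
#'   `"upper_bound"` (exchange flux in `[-uptake, 0]`)
#' @return object of class `environment_point`
#' @export
environment_point <- function(uptakes, mode = c("fixed", "upper_bound")) {
  mode <- match.arg(mode)
  if (any(uptakes < 0)) stop("uptake magnitudes must be >= 0")
  if (is.null(names(uptakes)) || any(!nzchar(names(uptakes))))
    stop("uptakes must be named by exchange reaction id")
  structure(list(uptakes = uptakes, mode = mode),
            class = "environment_point")
}

#' Apply an environment to a model
#'
#' The named uptakes are installed per the point's mode.  Every other
#' exchange that currently admits uptake (negative lower bound, i.e. the
#' model's distributed medium) is opened to the unconstrained value;
#' secretion bounds are left untouched.
#'
#' @param model a [metabolic_model()]
#' @param env an [environment_point()]
#' @param unconstrained_value magnitude used for non-limiting medium
#'   uptakes (default 1000)
#' @return modified model
#' @export
apply_environment <- function(model, env, unconstrained_value = 1000) {
  stopifnot(inherits(env, "environment_point"))
  ex <- exchange_reactions(model)
  unknown <- setdiff(names(env$uptakes), names(model$reactions))
  if (length(unknown)) stop("unknown reactions in environment: ",
                            paste(unknown, collapse = ", "))
  not_ex <- setdiff(names(env$uptakes), ex)
  if (length(not_ex)) stop("environment names non-exchange reactions: ",
                           paste(not_ex, collapse = ", "))
  for (rid in ex) {
    if (rid %in% names(env$uptakes)) next
    if (model$reactions[[rid]]$lb < 0)
      model$reactions[[rid]]$lb <- -unconstrained_value
  }
  for (rid in names(env$uptakes)) {
    u <- env$uptakes[[rid]]
    if (env$mode == "fixed") {
      model$reactions[[rid]]$lb <- -u
      model$reactions[[rid]]$ub <- -u
    } else {
      model$reactions[[rid]]$lb <- -u
      model$reactions[[rid]]$ub <- 0
    }
  }
  model
}

flux_solution <- function(fluxes, objective_value, status) {
  structure(list(fluxes = fluxes, objective_value = objective_value,
                 status = status), class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status,
      if (x$status == "optimal")
        paste0(", objective: ", format(x$objective_value, digits = 8)),
      "\n", sep = "")
  invisible(x)
}

#' Solve the flux balance analysis LP
#'
#' Maximises `sum_j c_j v_j` subject to steady state `S v = 0` and the
#' model's flux bounds.
#'
#' @param model a [metabolic_model()]
#' @param objective named numeric vector of objective coefficients; default
#'   is the model objective
#' @param maximize direction (default maximise)
#' @param tol solver tolerance
#' @return a `flux_solution` (fields `fluxes`, `objective_value`, `status`)
#' @export
solve_fba <- function(model, objective = model$objective, maximize = TRUE,
                      tol = MB_TOL) {
  if (!length(objective)) stop("empty objective")
  bad <- setdiff(names(objective), names(model$reactions))
  if (length(bad)) stop("objective references unknown reactions: ",
                        paste(bad, collapse = ", "))
  S <- stoichiometric_matrix(model)
  bounds <- reaction_bounds(model)
  obj <- stats::setNames(numeric(ncol(S)), colnames(S))
  obj[names(objective)] <- objective
  res <- lp_solve(obj, S, rep(0, nrow(S)), bounds[, "lb"], bounds[, "ub"],
                  maximize = maximize, tol = tol)
  if (res$status != "optimal")
    return(flux_solution(NULL, NA_real_, res$status))
  flux_solution(stats::setNames(res$x, colnames(S)), res$objval, "optimal")
}

#' Maximise a secretion flux at optimal growth
#'
#' Lexicographic two-stage solve: growth is optimised, fixed at its optimum
#' (within a 1e-9 relative slack), then the target exchange flux is
#' maximised.  With alternate growth optima this returns the one with the
#' largest target secretion.
#'
#' @param model a [metabolic_model()] (environment already applied)
#' @param growth_rxn id of the growth reaction
#' @param target_exchange id of the exchange to maximise
#' @param tol solver tolerance
#' @return a `flux_solution`; `objective_value` is the target flux, and
#'   the growth optimum is available as attribute `growth`
#' @export
max_secretion_at_optimal_growth <- function(model, growth_rxn,
                                            target_exchange, tol = MB_TOL) {
  g <- solve_fba(model, stats::setNames(1, growth_rxn), tol = tol)
  if (g$status != "optimal") return(g)
  gopt <- g$objective_value
  s <- fix_slack(gopt, tol)
  model <- set_reaction_bounds(model, growth_rxn, lb = gopt - s,
                               ub = gopt + s)
  out <- solve_fba(model, stats::setNames(1, target_exchange), tol = tol)
  attr(out, "growth") <- gopt
  out
}

#' Parsimonious flux minimisation
#'
#' Splits every reaction into irreversible halves and minimises the total
#' absolute flux subject to steady state and equality constraints pinning
#' the `fixed` reactions at their given values.
#'
#' @param model a [metabolic_model()]
#' @param fixed named numeric vector of reaction fluxes to hold (an
#'   equality row per reaction, slack `1e-9 * max(1, |value|)`)
#' @param tol solver tolerance
#' @return a `flux_solution` with net fluxes; `objective_value` is the
#'   minimised total absolute flux
#' @export
pfba_minimize <- function(model, fixed = numeric(), tol = MB_TOL) {
  S <- stoichiometric_matrix(model)
  bounds <- reaction_bounds(model)
  n <- ncol(S)
  lbp <- pmax(0, bounds[, "lb"]); ubp <- pmax(0, bounds[, "ub"])
  lbm <- pmax(0, -bounds[, "ub"]); ubm <- pmax(0, -bounds[, "lb"])
  A <- cbind(S, -S)
  b <- rep(0, nrow(S))
  if (length(fixed)) {
    bad <- setdiff(names(fixed), colnames(S))
    if (length(bad)) stop("fixed fluxes name unknown reactions: ",
                          paste(bad, collapse = ", "))
    for (rid in names(fixed)) {
      j <- match(rid, colnames(S))
      row <- numeric(2 * n); row[j] <- 1; row[n + j] <- -1
      A <- rbind(A, row)
      b <- c(b, fixed[[rid]])
    }
  }
  res <- lp_solve(rep(1, 2 * n), A, b, c(lbp, lbm), c(ubp, ubm),
                  maximize = FALSE, tol = tol)
  if (res$status != "optimal")
    return(flux_solution(NULL, NA_real_, res$status))
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  flux_solution(stats::setNames(v, colnames(S)), res$objval, "optimal")
}

#' Respiratory quotient at a given environment
#'
#' Three-level procedure: (1) maximise growth with the given biomass
#' reaction, (2) fix growth and maximise acetate secretion, (3) fix both
#' and apply parsimonious flux minimisation; RQ is then the CO2 secretion
#' flux divided by the O2 uptake magnitude of the parsimonious solution.
#'
#' @param model a [metabolic_model()] containing the biomass reaction
#' @param env an [environment_point()], or `NULL` when the model's bounds
#'   already encode the environment
#' @param bof_rxn growth reaction id
#' @param acetate_rxn,o2_rxn,co2_rxn exchange reaction ids (defaults follow
#'   the BiGG convention)
#' @param tol solver tolerance
#' @return scalar RQ; errors with class `multibof_infeasible` when growth
#'   is impossible and `multibof_undefined_rq` when the parsimonious O2
#'   uptake is zero
#' @export
respiratory_quotient <- function(model, env, bof_rxn,
                                 acetate_rxn = "EX_ac_e",
                                 o2_rxn = "EX_o2_e", co2_rxn = "EX_co2_e",
                                 tol = MB_TOL) {
  if (!is.null(env)) model <- apply_environment(model, env)
  sec <- max_secretion_at_optimal_growth(model, bof_rxn, acetate_rxn,
                                         tol = tol)
  if (sec$status != "optimal")
    stop(errorCondition(paste0("growth stage not optimal (", sec$status, ")"),
                        class = c("multibof_infeasible", "error")))
  gopt <- attr(sec, "growth")
  acopt <- sec$objective_value
  p <- pfba_minimize(model, fixed = stats::setNames(c(gopt, acopt),
                                                    c(bof_rxn, acetate_rxn)),
                     tol = tol)
  if (p$status != "optimal")
    stop(errorCondition("parsimonious stage infeasible",
                        class = c("multibof_infeasible", "error")))
  o2_uptake <- -p$fluxes[[o2_rxn]]
  co2_out <- p$fluxes[[co2_rxn]]
  if (o2_uptake <= 1e-6)
    stop(errorCondition("RQ undefined: zero O2 uptake at the parsimonious optimum",
                        class = c("multibof_undefined_rq", "error")))
  co2_out / o2_uptake
}

#' Export a flux solution as TSV
#'
#' @param solution a `flux_solution`
#' @param path destination
#' @return invisibly, `path`
#' @export
write_fluxes <- function(solution, path) {
  if (is.null(solution$fluxes)) stop("no fluxes to write (status ",
                                     solution$status, ")")
  utils::write.table(
    data.frame(reaction_id = names(solution$fluxes),
               flux = unname(solution$fluxes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
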