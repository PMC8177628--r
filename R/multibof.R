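# Multi-biomass methods.
#
# BTW (Biomass Tradeoff Weighting): every available biomass composition is
# attached as its own irreversible pseudo-reaction and all of them enter
# the FBA objective with coefficient 1; the LP distributes flux among them.
#
# HIP (plane interpolation): each biomass coefficient is an affine function
# of the nutrient-uptake coordinates, fit through measured (environment,
# composition) points; negative extrapolations are clamped to a fraction
# of a reference coefficient and the result is re-normalised to unit mass.
#
# HIP-I: fixed-point iteration of HIP -- the FBA optimum's uptake fluxes
# re-query the map until the uptake vector is self-consistent within eps.

#' Bundle a measured biomass composition with its environment
#'
#' @param environment named numeric vector of uptake magnitudes (one entry
#'   per environmental dimension, keyed by exchange reaction id)
#' @param composition a unit-mass [biomass_composition()]
#' @return object of class `bof_measurement`
#' @export
bof_measurement <- function(environment, composition) {
  m <- bof_mass(composition)
  if (abs(m - 1) > 1e-9)
    stop("measurement composition must be unit mass (got ",
         format(m, digits = 8), ")")
  structure(list(environment = environment, composition = composition),
            class = "bof_measurement")
}

#' Assemble a measurement set
#'
#' @param measurements list of [bof_measurement()] objects
#' @param dimensions ordered character vector of the n environmental
#'   dimensions (exchange reaction ids); every measurement must provide a
#'   coordinate for each
#' @return object of class `measurement_set`
#' @export
measurement_set <- function(measurements, dimensions) {
  for (m in measurements) {
    missing_dim <- setdiff(dimensions, names(m$environment))
    if (length(missing_dim))
      stop("measurement lacks coordinates for: ",
           paste(missing_dim, collapse = ", "))
  }
  structure(list(measurements = measurements, dimensions = dimensions),
            class = "measurement_set")
}

#' Install the BTW objective on a model
#'
#' Each composition is attached as an irreversible pseudo-reaction
#' (`BTW_<label>`) and the model objective is set to coefficient 1 on all
#' of them (zero elsewhere).
#'
#' @param model a [metabolic_model()]
#' @param bofs list of [biomass_composition()] objects (>= 1)
#' @return model with attribute `btw_reactions` naming the added reactions
#' @export
build_btw <- function(model, bofs) {
  if (!length(bofs)) stop("at least one biomass composition is required")
  ids <- character(length(bofs))
  for (i in seq_along(bofs)) {
    lab <- bofs[[i]]$label
    id <- paste0("BTW_", if (nzchar(lab)) lab else i)
    if (id %in% names(model$reactions)) id <- paste0(id, "_", i)
    model <- attach_bof(model, bofs[[i]], id)
    ids[i] <- id
  }
  model <- set_objective(model, stats::setNames(rep(1, length(ids)), ids))
  attr(model, "btw_reactions") <- ids
  model
}

#' Solve a BTW model
#'
#' @param model output of [build_btw()]
#' @param env optional [environment_point()] applied before solving
#' @param tol solver tolerance
#' @return a `flux_solution` with the per-composition flux split in field
#'   `bof_fluxes`; `objective_value` is their sum
#' @export
solve_btw <- function(model, env = NULL, tol = MB_TOL) {
  ids <- attr(model, "btw_reactions")
  if (is.null(ids)) stop("model has no BTW objective; call build_btw() first")
  if (!is.null(env)) model <- apply_environment(model, env)
  sol <- solve_fba(model, tol = tol)
  if (sol$status == "optimal") sol$bof_fluxes <- sol$fluxes[ids]
  sol
}

#' Fit the affine environment-to-composition map
#'
#' With exactly n+1 affinely independent measurements in n dimensions the
#' plane through the points is solved exactly; with more, a least-squares
#' plane is fit per coefficient.  Fewer than n+1 measurements error.
#'
#' @param ms a [measurement_set()]
#' @param reference reference [biomass_composition()] used for clamping
#'   negative extrapolations (conventionally the unlimited-environment
#'   composition)
#' @param clamp_fraction fraction of the reference coefficient substituted
#'   for a negative raw coefficient (default 0.01)
#' @return object of class `affine_bof_map`
#' @export
fit_affine_map <- function(ms, reference, clamp_fraction = 0.01) {
  stopifnot(inherits(ms, "measurement_set"))
  n <- length(ms$dimensions)
  k <- length(ms$measurements)
  if (k < n + 1)
    stop("need at least ", n + 1, " measurements for ", n,
         " dimensions; got ", k)
  fit_mode <- if (k == n + 1) "exact" else "least_squares"

  # shared compound universe keyed by (compound, side); missing entries
  # count as zero coefficient
  keys <- unique(do.call(rbind, lapply(ms$measurements, function(m)
    m$composition$entries[c("compound", "side", "group",
                            "molecular_weight")])))
  if (anyDuplicated(keys$compound))
    stop("side conflict across measurements for: ",
         paste(keys$compound[duplicated(keys$compound)], collapse = ", "))
  X <- cbind(1, do.call(rbind, lapply(ms$measurements, function(m)
    unname(m$environment[ms$dimensions]))))
  colnames(X) <- c("(intercept)", ms$dimensions)
  Y <- vapply(ms$measurements, function(m) {
    idx <- match(keys$compound, m$composition$entries$compound)
    ifelse(is.na(idx), 0, m$composition$entries$coefficient[idx])
  }, numeric(nrow(keys)))
  Y <- matrix(Y, nrow = nrow(keys))  # compounds x measurements

  qrX <- qr(X)
  if (qrX$rank < n + 1)
    stop("environment points are affinely dependent (collinear); ",
         "cannot fit a unique plane")
  coef <- t(qr.coef(qrX, t(Y)))  # compounds x (n+1)

  structure(list(coef = coef, keys = keys, dimensions = ms$dimensions,
                 fit_mode = fit_mode, reference = reference,
                 clamp_fraction = clamp_fraction),
            class = "affine_bof_map")
}

#' @export
print.affine_bof_map <- function(x, ...) {
  cat("<affine_bof_map> ", nrow(x$keys), " compounds over (",
      paste(x$dimensions, collapse = ", "), "), fit: ", x$fit_mode,
      ", clamp: ", x$clamp_fraction, " x reference\n", sep = "")
  invisible(x)
}

#' Raw affine evaluation of the map (no clamping, no renormalisation)
#'
#' @param object an `affine_bof_map`
#' @param env named coordinate vector or [environment_point()]
#' @param ... unused
#' @return data.frame with columns `compound`, `side`, `coefficient`
#'   (possibly negative)
#' @export
predict.affine_bof_map <- function(object, env, ...) {
  coords <- if (inherits(env, "environment_point")) env$uptakes else env
  missing_dim <- setdiff(object$dimensions, names(coords))
  if (length(missing_dim))
    stop("environment lacks dimensions: ",
         paste(missing_dim, collapse = ", "))
  x <- c(1, unname(coords[object$dimensions]))
  data.frame(compound = object$keys$compound, side = object$keys$side,
             coefficient = as.numeric(object$coef %*% x),
             stringsAsFactors = FALSE)
}

#' Interpolate a biomass composition at an environment point
#'
#' Evaluates the per-compound affine map at the given coordinates.  Any
#' negative raw coefficient is replaced by `clamp_fraction` times the
#' reference coefficient (zero when the reference lacks the compound), and
#' the result is re-normalised to unit consumed mass.
#'
#' @param map an [fit_affine_map()] result
#' @param env an [environment_point()] or named numeric coordinate vector
#'   covering the map's dimensions
#' @return a unit-mass [biomass_composition()]; attribute `clamped` lists
#'   the clamped compounds
#' @export
hip_bof <- function(map, env) {
  coords <- if (inherits(env, "environment_point")) env$uptakes else env
  missing_dim <- setdiff(map$dimensions, names(coords))
  if (length(missing_dim))
    stop("environment lacks dimensions: ",
         paste(missing_dim, collapse = ", "))
  x <- c(1, unname(coords[map$dimensions]))
  raw <- as.numeric(map$coef %*% x)
  ref <- map$reference$entries
  refc <- ref$coefficient[match(map$keys$compound, ref$compound)]
  refc[is.na(refc)] <- 0
  clamped <- raw < 0
  val <- ifelse(clamped, map$clamp_fraction * refc, raw)
  entries <- data.frame(compound = map$keys$compound, coefficient = val,
                        side = map$keys$side, group = map$keys$group,
                        molecular_weight = map$keys$molecular_weight,
                        stringsAsFactors = FALSE)
  lab <- paste0("HIP(", paste(map$dimensions,
                              signif(coords[map$dimensions], 6),
                              sep = "=", collapse = ","), ")")
  out <- normalize_unit_mass(biomass_composition(entries, label = lab))
  attr(out, "clamped") <- map$keys$compound[clamped]
  out
}

#' HIP: interpolated-biomass FBA at an environment point
#'
#' Generates the composition for the point with [hip_bof()], attaches it,
#' applies the environment in its stated mode, and solves FBA maximising
#' the generated biomass reaction.
#'
#' @param model a [metabolic_model()]
#' @param map an [fit_affine_map()] result
#' @param env an [environment_point()]
#' @param tol solver tolerance
#' @return a `flux_solution`; the generated composition is attached as
#'   attribute `bof`
#' @export
hip_solve <- function(model, map, env, tol = MB_TOL) {
  bof <- hip_bof(map, env)
  model <- attach_bof(model, bof, "BIOMASS_HIP")
  model <- apply_environment(model, env)
  sol <- solve_fba(model, stats::setNames(1, "BIOMASS_HIP"), tol = tol)
  attr(sol, "bof") <- bof
  sol
}

#' HIP-I: iterate HIP to a self-consistent uptake vector
#'
#' Starting from upper bounds `u` on the mapped uptakes, the composition
#' B_0 = hip_bof(u) is maximised under those bounds; the optimal uptake
#' magnitudes v_1 re-query the map for B_1, and so on.  The original
#' bounds `u` are kept at every iteration -- only the composition moves.
#' Convergence is the infinity norm over the map's dimensions:
#' `|v_1 - u| <= eps` terminates at iteration 0 (the HIP solution), then
#' `|v_k - v_{k-1}| <= eps`.
#'
#' @param model a [metabolic_model()]
#' @param map an [fit_affine_map()] result
#' @param u an [environment_point()] in `upper_bound` mode
#' @param eps convergence tolerance on the uptake vector (default 1e-3)
#' @param k_max maximum number of iterations (default 100)
#' @param deterministic_uptake when TRUE, each iterate's uptake vector is
#'   taken from a secondary lexicographic solve (maximal growth, then
#'   minimal total mapped uptake) instead of the raw FBA vertex
#' @param tol solver tolerance
#' @return object of class `hip_i_result`: fields `start`, `trajectory`
#'   (matrix, one row per v_k), `compositions` (B_0..B_k), `converged`,
#'   `iterations`, `epsilon`, `k_max`, `growth`, `solution`, `status`
#' @export
hip_i_solve <- function(model, map, u, eps = 1e-3, k_max = 100,
                        deterministic_uptake = FALSE, tol = MB_TOL) {
  stopifnot(inherits(u, "environment_point"))
  if (u$mode != "upper_bound")
    stop("HIP-I requires an upper_bound environment point")
  dims <- map$dimensions
  missing_dim <- setdiff(dims, names(u$uptakes))
  if (length(missing_dim))
    stop("environment lacks dimensions: ",
         paste(missing_dim, collapse = ", "))
  base <- apply_environment(model, u)

  solve_with <- function(bof) {
    m <- attach_bof(base, bof, "BIOMASS_HIP")
    sol <- solve_fba(m, stats::setNames(1, "BIOMASS_HIP"), tol = tol)
    if (sol$status == "optimal" && deterministic_uptake) {
      gopt <- sol$objective_value
      s <- fix_slack(gopt, tol)
      m2 <- set_reaction_bounds(m, "BIOMASS_HIP", lb = gopt - s,
                                ub = gopt + s)
      # minimise total mapped uptake magnitude (uptake = -flux, so
      # maximise the summed exchange fluxes)
      sol2 <- solve_fba(m2, stats::setNames(rep(1, length(dims)), dims),
                        tol = tol)
      if (sol2$status == "optimal") {
        sol2$objective_value <- gopt
        sol <- sol2
      }
    }
    sol
  }
  uptake_of <- function(sol)
    stats::setNames(pmax(0, -sol$fluxes[dims]), dims)

  v_prev <- u$uptakes[dims]
  bof <- hip_bof(map, u$uptakes)
  comps <- list(bof)
  traj <- matrix(numeric(0), ncol = length(dims),
                 dimnames = list(NULL, dims))
  result <- function(converged, iterations, sol, status) {
    rownames(traj) <- NULL
    structure(list(start = u, trajectory = traj, compositions = comps,
                   converged = converged, iterations = iterations,
                   epsilon = eps, k_max = k_max,
                   growth = if (status == "optimal") sol$objective_value
                            else NA_real_,
                   solution = sol, status = status),
              class = "hip_i_result")
  }

  k <- 0L
  repeat {
    sol <- solve_with(bof)
    if (sol$status != "optimal")
      return(result(FALSE, k, sol, sol$status))
    v_new <- uptake_of(sol)
    traj <- rbind(traj, v_new)
    if (max(abs(v_new - v_prev)) <= eps)
      return(result(TRUE, k, sol, "optimal"))
    if (k >= k_max)
      return(result(FALSE, k, sol, "optimal"))
    k <- k + 1L
    v_prev <- v_new
    bof <- hip_bof(map, v_new)
    comps[[length(comps) + 1L]] <- bof
  }
}

#' @export
print.hip_i_result <- function(x, ...) {
  cat("<hip_i_result> ", if (x$converged) "converged" else "NOT converged",
      " after ", x$iterations, " iteration(s); growth ",
      format(x$growth, digits = 8), "\n", sep = "")
  invisible(x)
}

#' Export a HIP-I trajectory as TSV
#'
#' @param result a `hip_i_result`
#' @param path destination
#' @return invisibly, `path`
#' @export
write_hip_i_trajectory <- function(result, path) {
  tr <- result$trajectory
  df <- data.frame(iteration = seq_len(nrow(tr)) - 1L, tr,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
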