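# Shared fixtures.  Everything is generated in code; nothing touches the
# network or large files.

# Toy model without the pre-attached biomass reactions (so each test
# attaches exactly the biomass source it wants).
base_toy <- function(spec = toy_spec(), seed = 1L) {
  m <- make_toy_model(spec, seed = seed)
  comps <- toy_compositions(m)
  m$reactions[c("BIOMASS_A", "BIOMASS_B")] <- NULL
  m$objective <- numeric()
  attr(m, "compositions") <- NULL
  list(model = m, bofs = comps)
}

# Three-point measurement set over (glucose, ammonium) built from the toy
# compositions: A at the unlimited coordinate, B at the nitrogen-limited
# one, and their mean at the carbon-limited one.
toy_measurements <- function(bofs) {
  ulc <- c(EX_glc_e = 18, EX_nh4_e = 8.5)
  nlc <- c(EX_glc_e = 13.5, EX_nh4_e = 1.5)
  clc <- c(EX_glc_e = 1.5, EX_nh4_e = 0.68)
  mid <- mean_bofs(bofs$A, bofs$B)
  list(ms = measurement_set(list(bof_measurement(ulc, bofs$A),
                                 bof_measurement(nlc, bofs$B),
                                 bof_measurement(clc, mid)),
                            names(ulc)),
       coords = list(UL = ulc, NL = nlc, CL = clc))
}

toy_map <- function(bofs, clamp_fraction = 0.01) {
  tm <- toy_measurements(bofs)
  fit_affine_map(tm$ms, reference = bofs$A,
                 clamp_fraction = clamp_fraction)
}

# Growth of a single fixed composition at an environment.
single_bof_growth <- function(model, bof, env, rxn = "BOF") {
  m <- apply_environment(attach_bof(model, bof, rxn), env)
  sol <- solve_fba(m, stats::setNames(1, rxn))
  if (sol$status != "optimal") return(NA_real_)
  sol$objective_value
}

# Independent LP oracle: enumerate basic solutions of
#   max c'x  s.t.  A x = b, lb <= x <= ub   (all bounds finite)
# by fixing (n - m) variables at a bound and solving the square system for
# the rest.  Exponential, so only for tiny problems; shares no code with
# the simplex path.
oracle_lp <- function(obj, A, b, lb, ub) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)), n - m >= 0)
  best <- -Inf; best_x <- NULL
  free_sets <- utils::combn(n, m, simplify = FALSE)
  for (fs in free_sets) {
    fixed <- setdiff(seq_len(n), fs)
    if (length(fixed)) {
      grids <- expand.grid(rep(list(c(1, 2)), length(fixed)))
    } else grids <- data.frame(row.names = 1)
    for (gi in seq_len(nrow(grids))) {
      x <- numeric(n)
      for (k in seq_along(fixed)) {
        x[fixed[k]] <- if (grids[gi, k] == 1) lb[fixed[k]] else ub[fixed[k]]
      }
      Af <- A[, fs, drop = FALSE]
      rhs <- b - as.numeric(A[, fixed, drop = FALSE] %*% x[fixed])
      sol <- tryCatch(solve(Af, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      x[fs] <- sol
      if (all(x >= lb - 1e-7) && all(x <= ub + 1e-7)) {
        val <- sum(obj * x)
        if (val > best + 1e-10) { best <- val; best_x <- x }
      }
    }
  }
  list(objval = best, x = best_x)
}
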