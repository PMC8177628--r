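# Dense two-phase primal simplex for the small LPs arising from
# constraint-based toy models.  Problems are solved in the bounded form
#
#     max/min  c'x   s.t.  A x = b,  lb <= x <= ub
#
# with lb/ub possibly infinite.  Variables are shifted/mirrored/split into
# nonnegative standard form; finite upper bounds become explicit slack rows.
# Bland's rule is enabled after an iteration threshold to guarantee
# termination on the (highly degenerate) flux cones we feed it.

LP_BLAND_AFTER <- 500L

#' Solve a bounded linear program
#'
#' Internal LP backend used by all flux-balance routines.  Solves
#' \code{max/min c'x} subject to \code{A x = b} and \code{lb <= x <= ub}.
#'
#' @param obj objective coefficient vector (length n)
#' @param A dense constraint matrix (m x n), rows are equalities
#' @param b right-hand side (length m)
#' @param lb,ub variable bounds; \code{-Inf}/\code{Inf} allowed
#' @param maximize logical; maximise (default) or minimise
#' @param tol feasibility/optimality tolerance
#' @return list with \code{status} (\code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}), \code{x} (primal solution, \code{NULL} unless
#'   optimal) and \code{objval}
#' @keywords internal
#' @noRd
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", x = NULL, objval = NA_real_))
  }
  cc <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  # --- transform to standard form: min c'y, M y = d, y >= 0 -------------
  # Each original variable contributes one or two standard columns; record
  # the inverse transform.
  cols <- list()  # per standard column: list(orig, sign, shift)
  Mcols <- list(); cstd <- numeric(0); ubstd <- numeric(0)
  d <- as.numeric(b)
  for (j in seq_len(n)) {
    aj <- A[, j, drop = TRUE]
    if (is.finite(lb[j])) {
      # y = x - lb >= 0
      d <- d - aj * lb[j]
      Mcols[[length(Mcols) + 1L]] <- aj
      cstd <- c(cstd, cc[j])
      ubstd <- c(ubstd, ub[j] - lb[j])
      cols[[length(cols) + 1L]] <- list(orig = j, sign = 1, shift = lb[j])
    } else if (is.finite(ub[j])) {
      # x = ub - y, y >= 0
      d <- d - aj * ub[j]
      Mcols[[length(Mcols) + 1L]] <- -aj
      cstd <- c(cstd, -cc[j])
      ubstd <- c(ubstd, Inf)
      cols[[length(cols) + 1L]] <- list(orig = j, sign = -1, shift = ub[j])
    } else {
      # free: x = y+ - y-
      Mcols[[length(Mcols) + 1L]] <- aj
      cstd <- c(cstd, cc[j]); ubstd <- c(ubstd, Inf)
      cols[[length(cols) + 1L]] <- list(orig = j, sign = 1, shift = 0)
      Mcols[[length(Mcols) + 1L]] <- -aj
      cstd <- c(cstd, -cc[j]); ubstd <- c(ubstd, Inf)
      cols[[length(cols) + 1L]] <- list(orig = j, sign = -1, shift = 0)
    }
  }
  nv <- length(Mcols)
  M <- if (nv) matrix(unlist(Mcols), nrow = m) else matrix(0, m, 0)

  # finite upper bounds -> slack rows y_j + s = U
  ubj <- which(is.finite(ubstd))
  nub <- length(ubj)
  if (nub) {
    M <- rbind(M, matrix(0, nub, nv))
    for (k in seq_len(nub)) M[m + k, ubj[k]] <- 1
    slack <- rbind(matrix(0, m, nub), diag(nub))
    M <- cbind(M, slack)
    cstd <- c(cstd, numeric(nub))
    d <- c(d, ubstd[ubj])
  }
  mm <- nrow(M); nn <- ncol(M)

  # make rhs nonnegative
  neg <- d < 0
  if (any(neg)) { M[neg, ] <- -M[neg, , drop = FALSE]; d[neg] <- -d[neg] }

  # --- phase 1 ----------------------------------------------------------
  Tab <- cbind(M, diag(mm), d)
  art <- nn + seq_len(mm)
  basis <- art
  cost1 <- c(numeric(nn), rep(1, mm))
  res1 <- simplex_run(Tab, basis, cost1, allow = rep(TRUE, nn + mm),
                      tol = tol)
  Tab <- res1$Tab; basis <- res1$basis
  if (res1$status != "optimal" || res1$objval > 1e-7) {
    return(list(status = "infeasible", x = NULL, objval = NA_real_))
  }
  # pivot remaining artificials out of the basis (or drop redundant rows)
  drop_rows <- integer(0)
  for (i in seq_len(nrow(Tab))) {
    if (basis[i] > nn) {
      piv <- which(abs(Tab[i, seq_len(nn)]) > 1e-10)
      piv <- setdiff(piv, basis)
      if (length(piv)) {
        Tab <- pivot_tableau(Tab, i, piv[1L])
        basis[i] <- piv[1L]
      } else {
        drop_rows <- c(drop_rows, i)
      }
    }
  }
  if (length(drop_rows)) {
    Tab <- Tab[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }

  # --- phase 2 ----------------------------------------------------------
  cost2 <- c(cstd, rep(0, mm))
  allow2 <- c(rep(TRUE, nn), rep(FALSE, mm))
  res2 <- simplex_run(Tab, basis, cost2, allow = allow2, tol = tol)
  if (res2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, objval = NA_real_))
  }
  Tab <- res2$Tab; basis <- res2$basis
  ncolT <- ncol(Tab)
  y <- numeric(nn + mm)
  y[basis] <- Tab[, ncolT]
  y <- pmax(y, 0)

  x <- numeric(n); shift <- numeric(n)
  for (k in seq_along(cols)) {
    tr <- cols[[k]]
    x[tr$orig] <- x[tr$orig] + tr$sign * y[k]
    if (tr$shift != 0) shift[tr$orig] <- tr$shift
  }
  x <- x + shift
  objval <- sum(obj * x)
  list(status = "optimal", x = x, objval = objval)
}

# one simplex run (min cost'y) on tableau Tab = [B | rhs] with given basis.
# allow marks columns permitted to enter.
simplex_run <- function(Tab, basis, cost, allow, tol = 1e-9,
                        maxit = 20000L) {
  ncolT <- ncol(Tab)
  ncols <- ncolT - 1L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > maxit) stop("simplex iteration limit reached")
    # reduced costs: c_j - c_B' B^{-1} A_j  (tableau is already B^{-1}A)
    cb <- cost[basis]
    red <- cost[seq_len(ncols)] - as.numeric(crossprod(cb, Tab[, seq_len(ncols), drop = FALSE]))
    red[!allow] <- Inf
    red[basis] <- Inf
    cand <- which(red < -tol)
    if (!length(cand)) {
      objval <- sum(cb * Tab[, ncolT])
      return(list(status = "optimal", Tab = Tab, basis = basis,
                  objval = objval))
    }
    enter <- if (iter > LP_BLAND_AFTER) cand[1L] else cand[which.min(red[cand])]
    colv <- Tab[, enter]
    pos <- which(colv > tol)
    if (!length(pos)) {
      return(list(status = "unbounded", Tab = Tab, basis = basis,
                  objval = NA_real_))
    }
    ratio <- Tab[pos, ncolT] / colv[pos]
    rmin <- min(ratio)
    ties <- pos[ratio <= rmin + tol]
    leave <- ties[which.min(basis[ties])]   # Bland tie-break
    Tab <- pivot_tableau(Tab, leave, enter)
    basis[leave] <- enter
  }
}

pivot_tableau <- function(Tab, i, j) {
  Tab[i, ] <- Tab[i, ] / Tab[i, j]
  other <- setdiff(seq_len(nrow(Tab)), i)
  if (length(other)) {
    Tab[other, ] <- Tab[other, , drop = FALSE] -
      outer(Tab[other, j], Tab[i, ])
  }
  Tab[, j] <- 0; Tab[i, j] <- 1
  Tab
}
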