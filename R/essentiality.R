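# Single-gene knockout screens via GPR evaluation, growth-ratio binning,
# the three-class fitness tally, and the angle-based similarity score
# against experimental knockout tables.

ESSENTIALITY_THRESHOLD <- 1e-2

#' Single-gene knockout screen
#'
#' For each gene, reactions whose GPR evaluates to inactive under the
#' knockout are bounded to zero and growth is re-optimised under the same
#' biomass method as the wild type.  HIP-I mutants re-run the full
#' iteration from the wild-type starting bounds, since a wild-type fixed
#' point can become unstable in a mutant network.  An infeasible mutant LP
#' scores grRatio 0 (essential); ratios marginally above 1 are clipped.
#'
#' @param model a [metabolic_model()]
#' @param bof_source a [biomass_composition()], a [build_btw()] model, or
#'   an [fit_affine_map()] result (with `iterate = TRUE` for HIP-I)
#' @param env an [environment_point()]
#' @param genes genes to screen (default: all model genes)
#' @param iterate use HIP-I when `bof_source` is a map
#' @param eps,k_max HIP-I settings
#' @param tol solver tolerance
#' @return object of class `knockout_table`: data.frame with columns
#'   `gene`, `grRatio`, `essential`; attributes `wild_type_growth`,
#'   `method`, `environment`
#' @export
single_gene_deletion <- function(model, bof_source, env,
                                 genes = model$genes, iterate = FALSE,
                                 eps = 1e-3, k_max = 100, tol = MB_TOL) {
  is_btw <- inherits(bof_source, "metabolic_model") &&
    !is.null(attr(bof_source, "btw_reactions"))
  # knockouts must hit the model that actually gets solved: for BTW that
  # is the bof_source model itself
  grow <- function(dead_rxns) {
    if (is_btw) {
      src <- bof_source
      for (rid in dead_rxns) src <- set_reaction_bounds(src, rid, 0, 0)
      prep <- prepare_cell(model, src, env, iterate, eps, k_max, tol)
    } else {
      m <- model
      for (rid in dead_rxns) m <- set_reaction_bounds(m, rid, 0, 0)
      prep <- prepare_cell(m, bof_source, env, iterate, eps, k_max, tol)
    }
    if (!prep$status %in% c("optimal", "not_converged")) return(0)
    max(0, prep$growth)
  }
  wt <- grow(character())
  if (wt <= tol * 10)
    stop("wild-type growth is zero at this environment; grRatio undefined")

  # map each gene to the reactions it can disable (GPR re-evaluated per
  # knockout; most genes touch few reactions)
  rules <- vapply(model$reactions, `[[`, character(1), "gpr")
  gene_in_rule <- lapply(model$reactions, function(r)
    if (is.na(r$gpr)) character() else gpr_genes(r$gpr))

  ratios <- vapply(genes, function(g) {
    hit <- names(model$reactions)[vapply(gene_in_rule, function(gs)
      g %in% gs, logical(1))]
    dead <- hit[!vapply(rules[hit], evaluate_gpr, logical(1), knocked = g)]
    if (!length(dead)) return(1)
    min(1, grow(dead) / wt)
  }, numeric(1))

  tab <- data.frame(gene = genes, grRatio = unname(ratios),
                    essential = unname(ratios) < ESSENTIALITY_THRESHOLD,
                    stringsAsFactors = FALSE)
  structure(tab, class = c("knockout_table", "data.frame"),
            wild_type_growth = wt,
            method = if (inherits(bof_source, "affine_bof_map")) {
              if (iterate) "hipi" else "hip"
            } else if (!is.null(attr(bof_source, "btw_reactions"))) "btw"
            else "fixed",
            environment = env)
}

#' Bin growth ratios into the five-interval histogram
#'
#' Intervals: [0, 0.01) / [0.01, 0.50] / (0.50, 0.88] / (0.88, 0.98] /
#' (0.98, 1].  Ratios are clipped to [0, 1] first.
#'
#' @param table a `knockout_table` (or data.frame with column `grRatio`)
#' @return named integer vector of five counts, summing to the gene count
#' @export
bin_ratios <- function(table) {
  r <- pmin(pmax(table$grRatio, 0), 1)
  counts <- c(
    "[0,0.01)"    = sum(r < 0.01),
    "[0.01,0.50]" = sum(r >= 0.01 & r <= 0.50),
    "(0.50,0.88]" = sum(r > 0.50 & r <= 0.88),
    "(0.88,0.98]" = sum(r > 0.88 & r <= 0.98),
    "(0.98,1]"    = sum(r > 0.98))
  storage.mode(counts) <- "integer"
  counts
}

#' Three-class fitness tally of a knockout screen
#'
#' Classes: essential [0, 0.01), intermediate [0.01, 0.98], no effect
#' (0.98, 1].
#'
#' @inheritParams bin_ratios
#' @return integer vector `c(essential, intermediate, no_effect)`
#' @export
three_group_vector <- function(table) {
  r <- pmin(pmax(table$grRatio, 0), 1)
  out <- c(essential = sum(r < 0.01),
           intermediate = sum(r >= 0.01 & r <= 0.98),
           no_effect = sum(r > 0.98))
  storage.mode(out) <- "integer"
  out
}

#' Three-class tally of experimental knockout scores
#'
#' Score classes: `s < -3` essential, `s` in `[-3, -1)` intermediate,
#' `s >= -1` no effect.
#'
#' @param scores numeric vector of per-gene fitness scores
#' @return integer vector `c(essential, intermediate, no_effect)`
#' @export
experimental_groups <- function(scores) {
  out <- c(essential = sum(scores < -3),
           intermediate = sum(scores >= -3 & scores < -1),
           no_effect = sum(scores >= -1))
  storage.mode(out) <- "integer"
  out
}

#' Angle similarity between two group tallies
#'
#' `theta = acos(u . v / (|u| |v|))`, in radians within [0, pi]; perfectly
#' aligned tallies score 0.  Symmetric and scale-invariant.
#'
#' @param u,v nonzero numeric vectors of equal length
#' @return angle in radians
#' @export
#' @examples
#' similarity_angle(c(237, 8, 1054), c(226, 60, 1013))  # ~0.0504
similarity_angle <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("similarity angle undefined for zero vectors")
  acos(max(-1, min(1, sum(u * v) / (nu * nv))))
}

#' Write a knockout table as TSV
#'
#' @param table a `knockout_table`
#' @param path destination
#' @return invisibly, `path`
#' @export
write_knockouts <- function(table, path) {
  r <- pmin(pmax(table$grRatio, 0), 1)
  bin_labels <- names(bin_ratios(table))
  idx <- ifelse(r < 0.01, 1L, ifelse(r <= 0.5, 2L,
               ifelse(r <= 0.88, 3L, ifelse(r <= 0.98, 4L, 5L))))
  out <- data.frame(gene = table$gene, grRatio = table$grRatio,
                    bin = bin_labels[idx], essential = table$essential)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an experimental score table
#'
#' TSV with columns `gene` and `score`.
#'
#' @param path file path
#' @return data.frame with columns `gene`, `score`
#' @export
read_score_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "score") %in% names(tab)))
    stop("score table needs columns 'gene' and 'score'")
  tab
}
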