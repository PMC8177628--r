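# Gene-protein-reaction rules: a small recursive-descent parser for boolean
# expressions over gene ids ("b0001 and (b0002 or b0003)").  `and` binds
# tighter than `or`, as in the SBML-FBC association semantics.

gpr_tokenize <- function(rule) {
  pat <- "\\(|\\)|[A-Za-z0-9_.:-]+"
  toks <- regmatches(rule, gregexpr(pat, rule))[[1]]
  rest <- gsub(pat, "", rule)
  if (grepl("[^[:space:]]", rest))
    stop("malformed GPR rule: ", rule)
  toks
}

gpr_parse <- function(rule) {
  toks <- gpr_tokenize(rule)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_or <- function() {
    node <- parse_and()
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      node <- list(op = "or", l = node, r = parse_and())
    }
    node
  }
  parse_and <- function() {
    node <- parse_atom()
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      node <- list(op = "and", l = node, r = parse_atom())
    }
    node
  }
  parse_atom <- function() {
    t <- take()
    if (is.na(t)) stop("malformed GPR rule (unexpected end): ", rule)
    if (t == "(") {
      node <- parse_or()
      if (!identical(take(), ")"))
        stop("malformed GPR rule (missing ')'): ", rule)
      return(node)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop("malformed GPR rule (unexpected '", t, "'): ", rule)
    list(op = "gene", id = t)
  }
  ast <- parse_or()
  if (pos <= length(toks))
    stop("malformed GPR rule (trailing tokens): ", rule)
  ast
}

gpr_eval_ast <- function(node, active) {
  switch(node$op,
         gene = if (node$id %in% names(active)) active[[node$id]] else TRUE,
         and  = gpr_eval_ast(node$l, active) && gpr_eval_ast(node$r, active),
         or   = gpr_eval_ast(node$l, active) || gpr_eval_ast(node$r, active))
}

gpr_ast_genes <- function(node) {
  if (node$op == "gene") return(node$id)
  c(gpr_ast_genes(node$l), gpr_ast_genes(node$r))
}

#' Genes referenced by a GPR rule
#'
#' @param rule GPR expression string
#' @return character vector of gene ids (possibly with duplicates removed)
#' @export
gpr_genes <- function(rule) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(character())
  unique(gpr_ast_genes(gpr_parse(rule)))
}

#' Evaluate a GPR rule under a gene knockout
#'
#' Standard boolean evaluation with the knocked-out gene set to FALSE and
#' every other gene TRUE.  An empty or missing rule is always active.
#'
#' @param rule GPR expression string (`and`/`or`/parentheses over gene ids)
#' @param knocked gene id(s) considered absent
#' @return logical: is the reaction still catalysable?
#' @export
#' @examples
#' evaluate_gpr("g1 or g2", "g1")            # TRUE
#' evaluate_gpr("g1 and g2", "g1")           # FALSE
evaluate_gpr <- function(rule, knocked = character()) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(TRUE)
  ast <- gpr_parse(rule)
  active <- stats::setNames(rep(FALSE, length(knocked)), knocked)
  gpr_eval_ast(ast, active)
}
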