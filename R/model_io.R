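# Model input/output: COBRA-style JSON and SBML Level 3 + FBC version 2.
# SBML ids follow the BiGG convention (M_/R_/G_ prefixes), stripped on read.
# Molecular weights, which neither standard carries natively, travel in
# species notes ("MOLECULAR_WEIGHT: <g/mol>"), mirroring how COBRA tools
# stash key-value pairs.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS  <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Read a constraint-based model
#'
#' @param path file path
#' @param format `"sbml-fbc"`, `"json"` or `"auto"` (by extension:
#'   `.xml`/`.sbml` vs `.json`)
#' @return a [metabolic_model()]
#' @export
read_model <- function(path, format = c("auto", "sbml-fbc", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xml = , sbml = "sbml-fbc", json = "json",
                     stop("cannot infer model format from extension: ", ext))
  }
  switch(format,
         "sbml-fbc" = read_model_sbml(path),
         "json" = read_model_json(path))
}

#' Write a constraint-based model
#'
#' The emitted file re-reads (with [read_model()]) to an equal model.
#'
#' @param model a [metabolic_model()]
#' @param path destination file
#' @param format `"sbml-fbc"`, `"json"` or `"auto"`
#' @return invisibly, `path`
#' @export
write_model <- function(model, path, format = c("auto", "sbml-fbc", "json")) {
  format <- match.arg(format)
  validate_model(model)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xml = , sbml = "sbml-fbc", json = "json",
                     stop("cannot infer model format from extension: ", ext))
  }
  switch(format,
         "sbml-fbc" = write_model_sbml(model, path),
         "json" = write_model_json(model, path))
  invisible(path)
}

# ---- JSON (community COBRA dialect) -----------------------------------

read_model_json <- function(path) {
  j <- tryCatch(jsonlite::read_json(path),
                error = function(e) stop("JSON parse failure in ", path,
                                         ": ", conditionMessage(e)))
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  chr_or_na <- function(x) if (is.null(x) || !nzchar(x)) NA_character_ else x
  mets <- do.call(rbind, lapply(j$metabolites, function(m) {
    data.frame(id = m$id, name = chr_or_na(m$name),
               compartment = chr_or_na(m$compartment),
               molecular_weight = num_or_na(m$notes$molecular_weight),
               formula = chr_or_na(m$formula), stringsAsFactors = FALSE)
  }))
  objective <- numeric()
  rxns <- lapply(j$reactions, function(r) {
    if (is.null(r$lower_bound) || is.null(r$upper_bound))
      stop("reaction '", r$id, "': missing flux bounds")
    st <- vapply(r$metabolites, as.numeric, numeric(1))
    reaction(r$id, st, lb = as.numeric(r$lower_bound),
             ub = as.numeric(r$upper_bound),
             gpr = chr_or_na(r$gene_reaction_rule),
             name = if (is.null(r$name)) r$id else r$name)
  })
  for (r in j$reactions) {
    oc <- num_or_na(r$objective_coefficient)
    if (!is.na(oc) && oc != 0) objective[[r$id]] <- oc
  }
  genes <- vapply(j$genes, `[[`, character(1), "id")
  metabolic_model(mets, rxns, genes = genes, objective = objective,
                  id = if (is.null(j$id)) "model" else j$id)
}

write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment,
                formula = m$formula, notes = list())
    if (!is.na(m$molecular_weight))
      out$notes$molecular_weight <- m$molecular_weight
    out
  })
  rxns <- lapply(model$reactions, function(r) {
    oc <- if (r$id %in% names(model$objective)) model$objective[[r$id]] else 0
    list(id = r$id, name = r$name, metabolites = as.list(r$stoich),
         lower_bound = r$lb, upper_bound = r$ub,
         gene_reaction_rule = if (is.na(r$gpr)) "" else r$gpr,
         objective_coefficient = oc)
  })
  j <- list(id = model$id, metabolites = mets,
            reactions = unname(rxns),
            genes = lapply(model$genes, function(g) list(id = g, name = g)))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
}

# ---- SBML L3 + FBC v2 -------------------------------------------------

sid_escape <- function(x) gsub("[^A-Za-z0-9_]", "__", x)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

num_fmt <- function(x) sprintf("%.17g", x)

write_model_sbml <- function(model, path) {
  mets <- model$metabolites
  comps <- unique(stats::na.omit(mets$compartment))
  if (!length(comps)) comps <- "c"
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
                   'fbc:required="false">'), SBML_NS, FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', sid_escape(model$id)),
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>',
            sid_escape(comps)),
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(mets))) {
    m <- mets[i, ]
    attrs <- sprintf(paste0('id="M_%s" name="%s" compartment="%s" ',
                            'hasOnlySubstanceUnits="false" ',
                            'boundaryCondition="false" constant="false"'),
                     sid_escape(m$id),
                     xml_escape(if (is.na(m$name)) m$id else m$name),
                     sid_escape(if (is.na(m$compartment)) "c" else m$compartment))
    if (!is.na(m$formula))
      attrs <- paste0(attrs, sprintf(' fbc:chemicalFormula="%s"', m$formula))
    if (!is.na(m$molecular_weight)) {
      lines <- c(lines,
        sprintf('      <species %s>', attrs),
        '        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
        sprintf('          <p>MOLECULAR_WEIGHT: %s</p>',
                num_fmt(m$molecular_weight)),
        '        </body></notes>',
        '      </species>')
    } else {
      lines <- c(lines, sprintf('      <species %s/>', attrs))
    }
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (r in model$reactions) {
    lines <- c(lines,
      sprintf('      <parameter id="R_%s_lb" value="%s" constant="true"/>',
              sid_escape(r$id), num_fmt(r$lb)),
      sprintf('      <parameter id="R_%s_ub" value="%s" constant="true"/>',
              sid_escape(r$id), num_fmt(r$ub)))
  }
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (r in model$reactions) {
    rid <- sid_escape(r$id)
    lines <- c(lines, sprintf(
      paste0('      <reaction id="R_%s" name="%s" reversible="%s" ',
             'fast="false" fbc:lowerFluxBound="R_%s_lb" ',
             'fbc:upperFluxBound="R_%s_ub">'),
      rid, xml_escape(r$name), if (r$lb < 0) "true" else "false", rid, rid))
    react <- r$stoich[r$stoich < 0]
    prod <- r$stoich[r$stoich > 0]
    if (length(react)) {
      lines <- c(lines, '        <listOfReactants>',
        sprintf(paste0('          <speciesReference species="M_%s" ',
                       'stoichiometry="%s" constant="true"/>'),
                sid_escape(names(react)), num_fmt(-unname(react))),
        '        </listOfReactants>')
    }
    if (length(prod)) {
      lines <- c(lines, '        <listOfProducts>',
        sprintf(paste0('          <speciesReference species="M_%s" ',
                       'stoichiometry="%s" constant="true"/>'),
                sid_escape(names(prod)), num_fmt(unname(prod))),
        '        </listOfProducts>')
    }
    if (!is.na(r$gpr) && nzchar(r$gpr)) {
      lines <- c(lines, '        <fbc:geneProductAssociation>',
                 gpr_to_fbc_xml(gpr_parse(r$gpr), indent = 10L),
                 '        </fbc:geneProductAssociation>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>')
  for (rid in names(model$objective)) {
    lines <- c(lines, sprintf(
      paste0('          <fbc:fluxObjective fbc:reaction="R_%s" ',
             'fbc:coefficient="%s"/>'),
      sid_escape(rid), num_fmt(model$objective[[rid]])))
  }
  lines <- c(lines,
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '    <fbc:listOfGeneProducts>')
  for (g in model$genes) {
    lines <- c(lines, sprintf(
      '      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
      sid_escape(g), xml_escape(g)))
  }
  lines <- c(lines, '    </fbc:listOfGeneProducts>',
             '  </model>', '</sbml>')
  writeLines(lines, path)
}

gpr_to_fbc_xml <- function(ast, indent) {
  pad <- strrep(" ", indent)
  if (ast$op == "gene") {
    return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                   pad, sid_escape(ast$id)))
  }
  tag <- if (ast$op == "and") "fbc:and" else "fbc:or"
  c(sprintf("%s<%s>", pad, tag),
    gpr_to_fbc_xml(ast$l, indent + 2L),
    gpr_to_fbc_xml(ast$r, indent + 2L),
    sprintf("%s</%s>", pad, tag))
}

strip_prefix <- function(x, prefix) {
  ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ", path,
                                           ": ", conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model_node, "xml_missing"))
    stop("SBML parse failure: no <model> element in ", path)
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- "model"

  # gene products: SBML id -> label
  gp_nodes <- xml2::xml_find_all(model_node, ".//fbc:geneProduct", ns)
  gp_ids <- xml2::xml_attr(gp_nodes, "fbc:id", ns)
  gp_labels <- xml2::xml_attr(gp_nodes, "fbc:label", ns)
  gp_labels[is.na(gp_labels)] <- strip_prefix(gp_ids[is.na(gp_labels)], "G_")
  gp_map <- stats::setNames(gp_labels, gp_ids)

  params <- xml2::xml_find_all(model_node, ".//s:parameter", ns)
  pmap <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  sp_nodes <- xml2::xml_find_all(model_node, ".//s:species", ns)
  sp_ids <- xml2::xml_attr(sp_nodes, "id")
  mw <- vapply(sp_nodes, function(sp) {
    p <- xml2::xml_text(xml2::xml_find_all(sp, ".//*"))
    hit <- grep("MOLECULAR_WEIGHT:", p, value = TRUE)
    if (length(hit)) as.numeric(sub(".*MOLECULAR_WEIGHT:\\s*", "", hit[1]))
    else NA_real_
  }, numeric(1))
  mets <- data.frame(
    id = strip_prefix(sp_ids, "M_"),
    name = xml2::xml_attr(sp_nodes, "name"),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    molecular_weight = mw,
    formula = xml2::xml_attr(sp_nodes, "fbc:chemicalFormula", ns),
    stringsAsFactors = FALSE)

  rx_nodes <- xml2::xml_find_all(model_node, ".//s:reaction", ns)
  rxns <- lapply(rx_nodes, function(rx) {
    rid_raw <- xml2::xml_attr(rx, "id")
    rid <- strip_prefix(rid_raw, "R_")
    lb_ref <- xml2::xml_attr(rx, "fbc:lowerFluxBound", ns)
    ub_ref <- xml2::xml_attr(rx, "fbc:upperFluxBound", ns)
    if (is.na(lb_ref) || is.na(ub_ref))
      stop("reaction '", rid_raw, "': missing FBC flux bounds")
    if (!lb_ref %in% names(pmap) || !ub_ref %in% names(pmap))
      stop("reaction '", rid_raw, "': bound parameter not found")
    sref <- function(xpath, sign) {
      nodes <- xml2::xml_find_all(rx, xpath, ns)
      if (!length(nodes)) return(numeric())
      stats::setNames(
        sign * as.numeric(xml2::xml_attr(nodes, "stoichiometry")),
        strip_prefix(xml2::xml_attr(nodes, "species"), "M_"))
    }
    st <- c(sref(".//s:listOfReactants/s:speciesReference", -1),
            sref(".//s:listOfProducts/s:speciesReference", +1))
    if (!length(st))
      stop("reaction '", rid_raw, "': empty stoichiometry")
    gpa <- xml2::xml_find_first(rx, ".//fbc:geneProductAssociation", ns)
    gpr <- if (inherits(gpa, "xml_missing")) NA_character_ else {
      child <- xml2::xml_find_first(gpa, "./*")
      fbc_assoc_to_gpr(child, gp_map, ns)
    }
    reaction(rid, st, lb = pmap[[lb_ref]], ub = pmap[[ub_ref]],
             gpr = gpr, name = {
               nm <- xml2::xml_attr(rx, "name")
               if (is.na(nm)) rid else nm
             })
  })

  objective <- numeric()
  fo_nodes <- xml2::xml_find_all(model_node, ".//fbc:fluxObjective", ns)
  for (fo in fo_nodes) {
    rid <- strip_prefix(xml2::xml_attr(fo, "fbc:reaction", ns), "R_")
    objective[[rid]] <- as.numeric(xml2::xml_attr(fo, "fbc:coefficient", ns))
  }

  metabolic_model(mets, rxns, genes = unname(gp_map),
                  objective = objective, id = model_id)
}

fbc_assoc_to_gpr <- function(node, gp_map, ns) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "fbc:geneProduct", ns)
    lab <- if (ref %in% names(gp_map)) gp_map[[ref]] else strip_prefix(ref, "G_")
    return(lab)
  }
  children <- xml2::xml_find_all(node, "./*")
  parts <- vapply(children, fbc_assoc_to_gpr, character(1),
                  gp_map = gp_map, ns = ns)
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}
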