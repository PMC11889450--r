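#' @importFrom xml2 read_xml xml_find_all xml_find_first xml_attr xml_name
#'   xml_children xml_text xml_add_child xml_new_root write_xml
NULL

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

# attribute lookup tolerant of fbc-prefixed names
.attrAny <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- match(c(name, paste0("fbc:", name)), names(at))
  hit <- hit[!is.na(hit)]
  if (length(hit)) unname(at[hit[1]]) else NA_character_
}

#' Read a constraint-based model from SBML
#'
#' Primary dialect: SBML Level 3 with the FBC (version 2) package, where
#' flux bounds are parameters referenced by \code{fbc:lowerFluxBound} /
#' \code{fbc:upperFluxBound} and gene associations are
#' \code{fbc:geneProductAssociation} trees. Level 2 files are accepted with
#' bounds taken from kineticLaw \code{LOWER_BOUND}/\code{UPPER_BOUND}
#' parameters (falling back to [-1000, 1000] or [0, 1000] by the
#' \code{reversible} attribute) and GPR rules from
#' \code{GENE_ASSOCIATION:} lines in reaction notes.
#'
#' @param path path to an SBML file.
#' @return a [MetabolicModel-class].
#' @export
readSBML <- function(path) {
  if (!file.exists(path))
    stop("cannot read SBML file: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("cannot parse SBML file ", path, ": ", conditionMessage(e),
         call. = FALSE))
  ns <- c(s = .SBML_NS, fbc = .FBC_NS)

  spNodes <- xml2::xml_find_all(
    doc, "//*[local-name()='listOfSpecies']/*[local-name()='species']")
  rxNodes <- xml2::xml_find_all(
    doc, "//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rxNodes) == 0L)
    stop("SBML file has no reactions (missing listOfReactions): ", path,
         call. = FALSE)
  if (length(spNodes) == 0L)
    stop("SBML file has no species (missing listOfSpecies): ", path,
         call. = FALSE)

  boundary <- xml2::xml_attr(spNodes, "boundaryCondition") %in% "true"
  mets <- data.frame(
    id = xml2::xml_attr(spNodes, "id"),
    name = ifelse(is.na(xml2::xml_attr(spNodes, "name")),
                  xml2::xml_attr(spNodes, "id"),
                  xml2::xml_attr(spNodes, "name")),
    compartment = xml2::xml_attr(spNodes, "compartment"),
    stringsAsFactors = FALSE)
  mets <- mets[!boundary, , drop = FALSE]

  pNodes <- xml2::xml_find_all(
    doc, "//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  params <- stats::setNames(as.numeric(xml2::xml_attr(pNodes, "value")),
                            xml2::xml_attr(pNodes, "id"))

  # fbc gene product labels (id -> label used in rules)
  gpNodes <- xml2::xml_find_all(doc, "//*[local-name()='geneProduct']")
  gpLabel <- stats::setNames(
    vapply(gpNodes, function(g) {
      lab <- .attrAny(g, "label")
      if (is.na(lab)) .attrAny(g, "id") else lab
    }, character(1)),
    vapply(gpNodes, .attrAny, character(1), name = "id"))

  nR <- length(rxNodes)
  ids <- xml2::xml_attr(rxNodes, "id")
  lb <- ub <- numeric(nR)
  gprText <- rep(NA_character_, nR)
  trip <- list()
  for (k in seq_len(nR)) {
    rx <- rxNodes[[k]]
    lbRef <- .attrAny(rx, "lowerFluxBound")
    ubRef <- .attrAny(rx, "upperFluxBound")
    if (!is.na(lbRef) && lbRef %in% names(params)) lb[k] <- params[[lbRef]]
    else if (!is.na(lbRef)) lb[k] <- suppressWarnings(as.numeric(lbRef))
    if (!is.na(ubRef) && ubRef %in% names(params)) ub[k] <- params[[ubRef]]
    else if (!is.na(ubRef)) ub[k] <- suppressWarnings(as.numeric(ubRef))
    if (is.na(lbRef) || is.na(ubRef)) {
      # Level 2 style: kineticLaw parameters, else reversibility default
      klp <- xml2::xml_find_all(rx, ".//*[local-name()='parameter']")
      klv <- stats::setNames(
        suppressWarnings(as.numeric(xml2::xml_attr(klp, "value"))),
        xml2::xml_attr(klp, "id"))
      rev2 <- !identical(xml2::xml_attr(rx, "reversible"), "false")
      if (is.na(lbRef))
        lb[k] <- if ("LOWER_BOUND" %in% names(klv)) klv[["LOWER_BOUND"]]
                 else if (rev2) -1000 else 0
      if (is.na(ubRef))
        ub[k] <- if ("UPPER_BOUND" %in% names(klv)) klv[["UPPER_BOUND"]]
                 else 1000
    }
    for (side in c("listOfReactants", "listOfProducts")) {
      srefs <- xml2::xml_find_all(
        rx, sprintf(".//*[local-name()='%s']/*[local-name()='speciesReference']",
                    side))
      if (!length(srefs)) next
      sp <- xml2::xml_attr(srefs, "species")
      st <- suppressWarnings(as.numeric(xml2::xml_attr(srefs, "stoichiometry")))
      st[is.na(st)] <- 1
      if (side == "listOfReactants") st <- -st
      keep <- sp %in% mets$id      # skip boundary species
      if (any(keep))
        trip[[length(trip) + 1L]] <-
          data.frame(i = match(sp[keep], mets$id), j = k, x = st[keep])
    }
    gpa <- xml2::xml_find_first(
      rx, ".//*[local-name()='geneProductAssociation']")
    if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      if (length(kids))
        gprText[k] <- .gpaToText(kids[[1]], gpLabel)
    } else {
      notes <- xml2::xml_find_first(rx, ".//*[local-name()='notes']")
      if (!inherits(notes, "xml_missing")) {
        txt <- xml2::xml_text(notes)
        m <- regmatches(txt,
                        regexpr("GENE_ASSOCIATION:[^\n<]*", txt))
        if (length(m)) {
          rule <- trimws(sub("^GENE_ASSOCIATION:", "", m[1]))
          if (nzchar(rule)) gprText[k] <- rule
        }
      }
    }
  }
  if (!length(trip))
    stop("SBML file has no stoichiometry (no speciesReference entries): ",
         path, call. = FALSE)
  tr <- do.call(rbind, trip)
  # sum duplicate (i,j) pairs, as sparseMatrix does
  S <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(nrow(mets), nR))

  # active objective
  objective <- character()
  fo <- xml2::xml_find_first(doc, "//*[local-name()='fluxObjective']")
  if (!inherits(fo, "xml_missing")) {
    rid <- .attrAny(fo, "reaction")
    if (!is.na(rid) && rid %in% ids) objective <- rid
  }

  MetabolicModel(metabolites = mets,
                 reactions = data.frame(id = ids, lb = lb, ub = ub,
                                        gpr = gprText,
                                        stringsAsFactors = FALSE),
                 S = S, objective = objective)
}

# fbc association subtree -> rule text
.gpaToText <- function(node, gpLabel) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- .attrAny(node, "geneProduct")
    lab <- gpLabel[gid]
    return(if (!is.na(lab)) unname(lab) else gid)
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, .gpaToText, character(1), gpLabel = gpLabel)
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

#' Write a model as SBML Level 3 + FBC v2
#'
#' Deterministic output: the same model always yields byte-identical files.
#'
#' @param model a [MetabolicModel-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSBML <- function(model, path) {
  num <- function(x) formatC(x, format = "g", digits = 15)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  L <- character()
  add <- function(...) L[[length(L) + 1L]] <<- paste0(...)
  add("<?xml version=\"1.0\" encoding=\"UTF-8\"?>")
  add("<sbml xmlns=\"", .SBML_NS, "\" xmlns:fbc=\"", .FBC_NS,
      "\" level=\"3\" version=\"1\" fbc:required=\"false\">")
  add("  <model id=\"model\" fbc:strict=\"true\">")
  comps <- unique(model@metabolites$compartment)
  comps[is.na(comps)] <- "c"
  comps <- unique(comps)
  add("    <listOfCompartments>")
  for (cp in comps)
    add("      <compartment id=\"", esc(cp),
        "\" constant=\"true\" size=\"1\"/>")
  add("    </listOfCompartments>")
  add("    <listOfSpecies>")
  for (i in seq_len(nrow(model@metabolites))) {
    m <- model@metabolites[i, ]
    cp <- if (is.na(m$compartment)) "c" else m$compartment
    add("      <species id=\"", esc(m$id), "\" name=\"", esc(m$name),
        "\" compartment=\"", esc(cp),
        "\" hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\"",
        " constant=\"false\"/>")
  }
  add("    </listOfSpecies>")
  add("    <listOfParameters>")
  for (i in seq_len(nrow(model@reactions))) {
    r <- model@reactions[i, ]
    add("      <parameter id=\"lb_", esc(r$id), "\" value=\"", num(r$lb),
        "\" constant=\"true\"/>")
    add("      <parameter id=\"ub_", esc(r$id), "\" value=\"", num(r$ub),
        "\" constant=\"true\"/>")
  }
  add("    </listOfParameters>")
  genes <- modelGenes(model)
  if (length(genes)) {
    add("    <fbc:listOfGeneProducts>")
    for (g in genes)
      add("      <fbc:geneProduct fbc:id=\"", esc(g), "\" fbc:label=\"",
          esc(g), "\"/>")
    add("    </fbc:listOfGeneProducts>")
  }
  add("    <listOfReactions>")
  rules <- model@gpr
  for (j in seq_len(nrow(model@reactions))) {
    r <- model@reactions[j, ]
    col <- model@S[, j]
    nz <- which(col != 0)
    add("      <reaction id=\"", esc(r$id), "\" reversible=\"",
        if (r$lb < 0) "true" else "false",
        "\" fast=\"false\" fbc:lowerFluxBound=\"lb_", esc(r$id),
        "\" fbc:upperFluxBound=\"ub_", esc(r$id), "\">")
    rea <- nz[col[nz] < 0]; pro <- nz[col[nz] > 0]
    if (length(rea)) {
      add("        <listOfReactants>")
      for (i in rea)
        add("          <speciesReference species=\"",
            esc(model@metabolites$id[i]), "\" stoichiometry=\"",
            num(-col[i]), "\" constant=\"true\"/>")
      add("        </listOfReactants>")
    }
    if (length(pro)) {
      add("        <listOfProducts>")
      for (i in pro)
        add("          <speciesReference species=\"",
            esc(model@metabolites$id[i]), "\" stoichiometry=\"",
            num(col[i]), "\" constant=\"true\"/>")
      add("        </listOfProducts>")
    }
    rule <- rules[[r$id]]
    if (!is.null(rule)) {
      add("        <fbc:geneProductAssociation>")
      add(.gpaXml(rule, indent = 10L))
      add("        </fbc:geneProductAssociation>")
    }
    add("      </reaction>")
  }
  add("    </listOfReactions>")
  if (length(model@objective)) {
    add("    <fbc:listOfObjectives fbc:activeObjective=\"obj\">")
    add("      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">")
    add("        <fbc:listOfFluxObjectives>")
    add("          <fbc:fluxObjective fbc:reaction=\"",
        esc(model@objective), "\" fbc:coefficient=\"1\"/>")
    add("        </fbc:listOfFluxObjectives>")
    add("      </fbc:objective>")
    add("    </fbc:listOfObjectives>")
  }
  add("  </model>")
  add("</sbml>")
  writeLines(unlist(L), path, useBytes = TRUE)
  invisible(path)
}

.gpaXml <- function(rule, indent) {
  pad <- strrep(" ", indent)
  if (is.character(rule))
    return(paste0(pad, "<fbc:geneProductRef fbc:geneProduct=\"", rule,
                  "\"/>"))
  inner <- vapply(rule$children, .gpaXml, character(1), indent = indent + 2L)
  paste0(pad, "<fbc:", rule$op, ">\n",
         paste(inner, collapse = "\n"),
         "\n", pad, "</fbc:", rule$op, ">")
}
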