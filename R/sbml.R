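#' Export a Boolean network as SBML-qual (best effort)
#'
#' Writes an SBML Level 3 qualitative-models document: one qualitative species
#' per node (with `initialLevel` for clamped nodes) and one transition per
#' node whose function term is the disjunctive normal form of its truth table
#' in MathML.  The export covers logical structure only and is intended for
#' interchange with logical-modeling tools; there is no importer.
#'
#' @param model A `bnet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml_qual <- function(model, path) {
  stopifnot(inherits(model, "bnet"))
  qual_ns <- "http://www.sbml.org/sbml/level3/version1/qual/version1"
  math_ns <- "http://www.w3.org/1998/Math/MathML"
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:qual" = qual_ns,
    level = "3", version = "1", "qual:required" = "true"
  )
  mdl <- xml2::xml_add_child(doc, "model", id = "boolean_network")
  los <- xml2::xml_add_child(mdl, "qual:listOfQualitativeSpecies")
  for (nd in model$nodes) {
    clamped <- nd %in% names(model$clamps)
    sp <- xml2::xml_add_child(los, "qual:qualitativeSpecies",
                              "qual:id" = nd, "qual:maxLevel" = "1",
                              "qual:constant" = if (clamped) "true" else "false")
    if (clamped) {
      xml2::xml_set_attr(sp, "qual:initialLevel",
                         as.character(model$clamps[[nd]]))
    }
  }
  lot <- xml2::xml_add_child(mdl, "qual:listOfTransitions")
  for (r in model$rules) {
    tr <- xml2::xml_add_child(lot, "qual:transition",
                              "qual:id" = paste0("tr_", r$target))
    if (length(r$inputs)) {
      loi <- xml2::xml_add_child(tr, "qual:listOfInputs")
      for (inp in r$inputs) {
        xml2::xml_add_child(loi, "qual:input",
                            "qual:qualitativeSpecies" = inp,
                            "qual:transitionEffect" = "none")
      }
    }
    loo <- xml2::xml_add_child(tr, "qual:listOfOutputs")
    xml2::xml_add_child(loo, "qual:output",
                        "qual:qualitativeSpecies" = r$target,
                        "qual:transitionEffect" = "assignmentLevel")
    loft <- xml2::xml_add_child(tr, "qual:listOfFunctionTerms")
    xml2::xml_add_child(loft, "qual:defaultTerm", "qual:resultLevel" = "0")
    ft <- xml2::xml_add_child(loft, "qual:functionTerm",
                              "qual:resultLevel" = "1")
    math <- xml2::xml_add_child(ft, "math", xmlns = math_ns)
    expr <- if (!is.null(r$expr)) r$expr else .parse_logic_expr(.table_to_dnf(r))
    .add_mathml(math, expr)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# MathML rendering of a logical expression: node X becomes the predicate
# <eq/> X 1, connectives become <and/>, <or/>, <not/>.
.add_mathml <- function(parent, e) {
  if (is.symbol(e)) {
    ap <- xml2::xml_add_child(parent, "apply")
    xml2::xml_add_child(ap, "eq")
    xml2::xml_add_child(ap, "ci", as.character(e))
    xml2::xml_add_child(ap, "cn", "1", type = "integer")
    return(invisible(NULL))
  }
  if (is.numeric(e)) {
    xml2::xml_add_child(parent, "cn", as.character(as.integer(e)),
                        type = "integer")
    return(invisible(NULL))
  }
  op <- as.character(e[[1]])
  if (op == "(") return(.add_mathml(parent, e[[2]]))
  ap <- xml2::xml_add_child(parent, "apply")
  if (op == "!") {
    xml2::xml_add_child(ap, "not")
    .add_mathml(ap, e[[2]])
  } else {
    xml2::xml_add_child(ap, if (op == "&") "and" else "or")
    .add_mathml(ap, e[[2]])
    .add_mathml(ap, e[[3]])
  }
  invisible(NULL)
}
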