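#' Read an expression matrix from TSV
#'
#' Expects a tab-separated table whose header row holds sample IDs and
#' whose first column holds gene IDs, plus a sample sheet TSV with
#' columns `sample` and `group`. Values are validated against the
#' expression-matrix invariants and the reader/writer pair round-trips
#' finite values bit-identically.
#'
#' @param path expression TSV.
#' @param samples_path sample-sheet TSV.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, samples_path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression table needs gene + sample columns")
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifier in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(tab[-1], is.numeric, logical(1)))[1]
    stop("non-numeric intensities in column '", names(tab)[-1][bad], "'")
  }
  rownames(m) <- genes
  sheet <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(sheet))) {
    stop("sample sheet needs columns 'sample' and 'group'")
  }
  expression_matrix(m, stats::setNames(sheet$group, sheet$sample))
}

#' Write an expression matrix (and its sample sheet) to TSV
#'
#' @param mat an [expression_matrix()].
#' @param path expression TSV to write.
#' @param samples_path optional sample-sheet TSV to write.
#' @export
write_expression_tsv <- function(mat, path, samples_path = NULL) {
  df <- data.frame(gene = rownames(mat$values), mat$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(samples_path)) {
    utils::write.table(
      data.frame(sample = colnames(mat$values), group = mat$groups),
      samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a composition scan to CSV
#'
#' Emits a self-describing header (units, scenario, doses, seedless
#' deterministic provenance) followed by ratio, pAKT and pERK percent
#' inhibition columns.
#'
#' @param scan a [composition_scan()] result.
#' @param path output CSV.
#' @export
write_scan_csv <- function(scan, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# composition scan: percent inhibition vs HER3/HER2 ratio",
    paste0("# scenario: ", attr(scan, "scenario")),
    "# units: ratio dimensionless; inhibition percent of drug-free control"),
    con)
  utils::write.table(as.data.frame(scan), con, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a reaction network to SBML Level 3
#'
#' One SBML species per network species (nM), one reaction per network
#' reaction with an explicit mass-action kinetic law; boundary species
#' are flagged `boundaryCondition="true"`. Only mass-action laws are
#' encodable; anything else raises an unsupported-feature error.
#'
#' @param network a [reaction_network()].
#' @param path output file.
#' @param init optional named initial concentrations; defaults to zeros.
#' @export
export_sbml <- function(network, path, init = NULL) {
  if (is.null(init)) {
    init <- stats::setNames(rep(0, length(network$species)),
                            network$species)
  }
  sid <- function(nm) {
    x <- gsub("[^A-Za-z0-9_]", "_", nm)
    if (grepl("^[0-9]", x)) x <- paste0("s_", x)
    x
  }
  ids <- vapply(network$species, sid, "")
  if (anyDuplicated(ids)) stop("species names collide after SBML id mangling")
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = "erbb_network",
                               substanceUnits = "nanomole",
                               timeUnits = "minute")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1",
                      constant = "true")
  lspec <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_along(network$species)) {
    nm <- network$species[i]
    xml2::xml_add_child(
      lspec, "species", id = ids[i], name = nm, compartment = "cell",
      initialConcentration = format(unname(init[nm]), digits = 17),
      hasOnlySubstanceUnits = "false",
      boundaryCondition = if (nm %in% network$boundary) "true" else "false",
      constant = "false")
  }
  lpar <- xml2::xml_add_child(model, "listOfParameters")
  for (pn in names(network$params)) {
    xml2::xml_add_child(lpar, "parameter", id = sid(pn),
                        value = format(network$params[[pn]], digits = 17),
                        constant = "true")
  }
  lrx <- xml2::xml_add_child(model, "listOfReactions")
  for (rx in network$reactions) {
    if (any(rx$reactants != round(rx$reactants)) ||
        any(rx$products != round(rx$products))) {
      stop("reaction '", rx$name,
           "': non-integer stoichiometry is not encodable as mass action")
    }
    rn <- xml2::xml_add_child(lrx, "reaction", id = sid(rx$name),
                              name = rx$name, reversible = "false")
    if (length(rx$reactants)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (j in seq_along(rx$reactants)) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = sid(names(rx$reactants)[j]),
                            stoichiometry = format(rx$reactants[[j]]),
                            constant = "true")
      }
    }
    if (length(rx$products)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (j in seq_along(rx$products)) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = sid(names(rx$products)[j]),
                            stoichiometry = format(rx$products[[j]]),
                            constant = "true")
      }
    }
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(
      kl, "math", xmlns = "http://www.w3.org/1998/Math/MathML")
    terms <- c(sid(rx$rate),
               rep(vapply(names(rx$reactants), sid, ""),
                   times = rx$reactants))
    if (length(terms) == 1) {
      xml2::xml_add_child(math, "ci", terms)
    } else {
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "times")
      for (tm in terms) xml2::xml_add_child(ap, "ci", tm)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Re-import an SBML export as a reaction network
#'
#' Independent parser used to verify the SBML writer: reconstructs
#' species (with boundary flags), parameters and mass-action reactions
#' from the document and returns a [reaction_network()] plus the initial
#' concentrations. Conservation groups are not encoded in SBML and come
#' back empty.
#'
#' @param path SBML file written by [export_sbml()] (or an equivalent
#'   Level 3 document with mass-action kinetic laws).
#' @return list with elements `network` and `init`.
#' @export
import_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  sp_nodes <- xml2::xml_find_all(doc, ".//s:species", ns)
  ids <- xml2::xml_attr(sp_nodes, "id")
  nms <- xml2::xml_attr(sp_nodes, "name")
  nms[is.na(nms)] <- ids[is.na(nms)]
  boundary <- nms[xml2::xml_attr(sp_nodes, "boundaryCondition") == "true"]
  init <- stats::setNames(
    as.numeric(xml2::xml_attr(sp_nodes, "initialConcentration")), nms)
  id2name <- stats::setNames(nms, ids)
  par_nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter",
                                  ns)
  params <- stats::setNames(
    as.numeric(xml2::xml_attr(par_nodes, "value")),
    xml2::xml_attr(par_nodes, "id"))
  rx_nodes <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  reactions <- lapply(rx_nodes, function(node) {
    nm <- xml2::xml_attr(node, "name")
    if (is.na(nm)) nm <- xml2::xml_attr(node, "id")
    refs <- function(which) {
      rr <- xml2::xml_find_all(
        node, paste0("./s:listOf", which, "/s:speciesReference"), ns)
      if (!length(rr)) return(numeric())
      stats::setNames(
        as.numeric(xml2::xml_attr(rr, "stoichiometry")),
        id2name[xml2::xml_attr(rr, "species")])
    }
    ci <- xml2::xml_text(
      xml2::xml_find_all(node, ".//s:kineticLaw//*[local-name()='ci']",
                         ns))
    rate <- intersect(ci, names(params))
    if (length(rate) != 1) {
      stop("reaction '", nm, "': kinetic law is not simple mass action")
    }
    reaction(nm, refs("Reactants"), refs("Products"), rate)
  })
  net <- reaction_network(unname(nms), reactions, params,
                          boundary = unname(boundary))
  list(network = net, init = init)
}

#' Write an end-to-end differential table to CSV
#'
#' @param results a [differential_result()] data.frame.
#' @param path output CSV.
#' @param contrast label recorded in the header.
#' @export
write_differential_csv <- function(results, path, contrast = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# differential expression (linear fold change; Student's t on log2)",
    paste0("# contrast: ", contrast),
    "# significance: raw p < 0.05, no multiple-testing correction"), con)
  utils::write.table(results, con, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
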