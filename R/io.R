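SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Load a metabolic model from file
#'
#' Dispatches on the file extension: `.xml`/`.sbml` are parsed as SBML
#' Level 3 with the flux-bounds (fbc) extension, `.json` as the flat JSON
#' dialect written by [write_model_json()].  The biomass reaction is taken
#' from the fbc objective (or the JSON field); failing that, a reaction whose
#' id or name matches `biomass|growth` (case-insensitive) is used.
#'
#' @param path path to an SBML or JSON model file.
#' @param namespace metabolite identifier namespace of the model source.
#' @return A [metabolic_model()].
#' @export
load_model <- function(path, namespace = c("bigg", "modelseed", "metanetx")) {
  namespace <- match.arg(namespace)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         xml = ,
         sbml = read_model_sbml(path, namespace),
         json = read_model_json(path, namespace),
         stop("unrecognised model format: .", ext,
              " (expected .xml/.sbml or .json)"))
}

## -- SBML -----------------------------------------------------------------

#' Read an SBML Level 3 (fbc) model
#'
#' Parses the subset of SBML used by constraint-based reconstructions:
#' compartments, species (with `boundaryCondition`, fbc charge and chemical
#' formula), reactions with fbc flux-bound parameters, and the active fbc
#' objective.  Conventional `M_`/`R_` SId prefixes are stripped.  Species
#' flagged `boundaryCondition="true"` are removed from reaction
#' stoichiometries (they are not balanced), which leaves exchange reactions
#' touching a single metabolite.
#'
#' @inheritParams load_model
#' @return A [metabolic_model()].
#' @export
read_model_sbml <- function(path, namespace = c("bigg", "modelseed", "metanetx")) {
  namespace <- match.arg(namespace)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure: ",
                                           conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model_node, "xml_missing")) stop("SBML parse failure: no <model>")
  model_id <- xml2::xml_attr(model_node, "id") %|na|% basename(path)

  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  attr1 <- function(nodes, name) {
    vapply(nodes, function(nd) {
      a <- xml2::xml_attrs(nd)
      hit <- which(names(a) == name | endsWith(names(a), paste0(":", name)))
      if (length(hit)) a[[hit[1]]] else NA_character_
    }, character(1))
  }
  mets <- tibble::tibble(
    id = strip_sid(attr1(sp, "id")),
    name = attr1(sp, "name"),
    compartment = attr1(sp, "compartment"),
    formula = attr1(sp, "chemicalFormula"),
    charge = suppressWarnings(as.numeric(attr1(sp, "charge"))),
    boundary = attr1(sp, "boundaryCondition") %in% "true")
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]

  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  par_val <- stats::setNames(
    suppressWarnings(as.numeric(attr1(pars, "value"))), attr1(pars, "id"))

  boundary_ids <- mets$id[mets$boundary]
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  parse_refs <- function(nd, xpath, sign) {
    refs <- xml2::xml_find_all(nd, xpath)
    if (!length(refs)) return(numeric(0))
    ids <- strip_sid(vapply(refs, xml2::xml_attr, character(1), "species"))
    coef <- vapply(refs, function(r) {
      s <- xml2::xml_attr(r, "stoichiometry")
      if (is.na(s)) 1 else as.numeric(s)
    }, numeric(1))
    stats::setNames(sign * coef, ids)
  }
  rxns <- purrr::map_dfr(rx_nodes, function(nd) {
    a <- xml2::xml_attrs(nd)
    getatt <- function(name) {
      hit <- which(names(a) == name | endsWith(names(a), paste0(":", name)))
      if (length(hit)) a[[hit[1]]] else NA_character_
    }
    st <- c(parse_refs(nd, "./listOfReactants/speciesReference", -1),
            parse_refs(nd, "./listOfProducts/speciesReference", +1))
    st <- st[!names(st) %in% boundary_ids]
    reversible <- identical(getatt("reversible"), "true")
    lbp <- getatt("lowerFluxBound"); ubp <- getatt("upperFluxBound")
    lb <- if (!is.na(lbp) && lbp %in% names(par_val)) par_val[[lbp]]
          else if (reversible) -1000 else 0
    ub <- if (!is.na(ubp) && ubp %in% names(par_val)) par_val[[ubp]] else 1000
    tibble::tibble(id = strip_sid(getatt("id")),
                   name = getatt("name") %|na|% strip_sid(getatt("id")),
                   stoichiometry = list(st),
                   lower_bound = lb, upper_bound = ub,
                   gene_rule = NA_character_)
  })

  fo <- xml2::xml_find_first(
    doc, ".//listOfObjectives//listOfFluxObjectives/fluxObjective")
  biomass <- NA_character_
  if (!inherits(fo, "xml_missing")) {
    a <- xml2::xml_attrs(fo)
    hit <- which(names(a) == "reaction" | endsWith(names(a), ":reaction"))
    if (length(hit)) biomass <- strip_sid(a[[hit[1]]])
  }
  if (is.na(biomass)) biomass <- guess_biomass(rxns)

  mets <- mets[!mets$boundary, , drop = FALSE]
  metabolic_model(mets, rxns, biomass, namespace, id = model_id)
}

strip_sid <- function(x) sub("^[MR]_", "", x)

`%|na|%` <- function(a, b) ifelse(is.na(a), b, a)

guess_biomass <- function(rxns) {
  hit <- grepl("biomass|growth", rxns$id, ignore.case = TRUE) |
    grepl("biomass|growth", rxns$name %|na|% "", ignore.case = TRUE)
  if (!any(hit))
    stop("no biomass reaction: no fbc/JSON objective set and no reaction ",
         "id or name matches the heuristic pattern 'biomass|growth'")
  rxns$id[which(hit)[1]]
}

#' Write a model as SBML Level 3 with fbc flux bounds
#'
#' @param m a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_sbml <- function(m, path) {
  validate_model(m)
  sid <- function(x) paste0(ifelse(grepl("^[A-Za-z_]", x), "", "_"), x)
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_CORE_NS, "xmlns:fbc" = SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mod <- xml2::xml_add_child(doc, "model", id = sid(m$id),
                             "fbc:strict" = "true")
  lc <- xml2::xml_add_child(mod, "listOfCompartments")
  for (cmp in unique(m$metabolites$compartment))
    xml2::xml_add_child(lc, "compartment", id = sid(cmp), constant = "true")
  ls <- xml2::xml_add_child(mod, "listOfSpecies")
  for (i in seq_len(nrow(m$metabolites))) {
    mt <- m$metabolites[i, ]
    nd <- xml2::xml_add_child(
      ls, "species", id = paste0("M_", mt$id), name = mt$name,
      compartment = sid(mt$compartment), hasOnlySubstanceUnits = "false",
      boundaryCondition = if (isTRUE(mt$boundary)) "true" else "false",
      constant = "false")
    if (!is.na(mt$formula)) xml2::xml_set_attr(nd, "fbc:chemicalFormula", mt$formula)
    if (!is.na(mt$charge))
      xml2::xml_set_attr(nd, "fbc:charge", format(as.integer(mt$charge)))
  }
  lp <- xml2::xml_add_child(mod, "listOfParameters")
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  for (i in seq_len(nrow(m$reactions))) {
    r <- m$reactions[i, ]
    xml2::xml_add_child(lp, "parameter", id = paste0("R_", r$id, "_lb"),
                        value = num(r$lower_bound), constant = "true")
    xml2::xml_add_child(lp, "parameter", id = paste0("R_", r$id, "_ub"),
                        value = num(r$upper_bound), constant = "true")
  }
  lr <- xml2::xml_add_child(mod, "listOfReactions")
  for (i in seq_len(nrow(m$reactions))) {
    r <- m$reactions[i, ]
    nd <- xml2::xml_add_child(
      lr, "reaction", id = paste0("R_", r$id), name = r$name,
      reversible = if (r$lower_bound < 0) "true" else "false", fast = "false")
    xml2::xml_set_attr(nd, "fbc:lowerFluxBound", paste0("R_", r$id, "_lb"))
    xml2::xml_set_attr(nd, "fbc:upperFluxBound", paste0("R_", r$id, "_ub"))
    st <- r$stoichiometry[[1]]
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      lre <- xml2::xml_add_child(nd, "listOfReactants")
      for (k in seq_along(subs))
        xml2::xml_add_child(lre, "speciesReference",
                            species = paste0("M_", names(subs)[k]),
                            stoichiometry = num(-subs[[k]]), constant = "true")
    }
    if (length(prods)) {
      lpr <- xml2::xml_add_child(nd, "listOfProducts")
      for (k in seq_along(prods))
        xml2::xml_add_child(lpr, "speciesReference",
                            species = paste0("M_", names(prods)[k]),
                            stoichiometry = num(prods[[k]]), constant = "true")
    }
  }
  lo <- xml2::xml_add_child(mod, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lf, "fbc:fluxObjective",
                      "fbc:reaction" = paste0("R_", m$biomass_reaction_id),
                      "fbc:coefficient" = "1")
  xml2::write_xml(doc, path)
  invisible(path)
}

## -- JSON -----------------------------------------------------------------

#' Read a model from the flat JSON dialect
#'
#' The dialect mirrors the cobra JSON schema: top-level `id`, `namespace`,
#' `biomass_reaction_id`, a `metabolites` array and a `reactions` array whose
#' entries carry a `metabolites` (or `stoichiometry`) map of coefficients plus
#' `lower_bound`/`upper_bound`.
#'
#' @inheritParams load_model
#' @param namespace fallback namespace if the file does not declare one.
#' @return A [metabolic_model()].
#' @export
read_model_json <- function(path, namespace = c("bigg", "modelseed", "metanetx")) {
  namespace <- match.arg(namespace)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("JSON parse failure: ",
                                           conditionMessage(e)))
  ns <- doc$namespace %||% namespace
  mets <- purrr::map_dfr(doc$metabolites, function(x) tibble::tibble(
    id = x$id, name = x$name %||% x$id, compartment = x$compartment,
    formula = x$formula %||% NA_character_,
    charge = as.numeric(x$charge %||% NA_real_),
    boundary = isTRUE(x$boundary)))
  rxns <- purrr::map_dfr(doc$reactions, function(x) {
    st <- unlist(x$metabolites %||% x$stoichiometry)
    tibble::tibble(
      id = x$id, name = x$name %||% x$id,
      stoichiometry = list(stats::setNames(as.numeric(st), names(st))),
      lower_bound = as.numeric(x$lower_bound %||% -1000),
      upper_bound = as.numeric(x$upper_bound %||% 1000),
      gene_rule = x$gene_rule %||% NA_character_)
  })
  biomass <- doc$biomass_reaction_id %||% guess_biomass(rxns)
  metabolic_model(mets, rxns, biomass, ns, id = doc$id %||% basename(path))
}

#' Write a model to the flat JSON dialect
#'
#' @inheritParams write_model_sbml
#' @return `path`, invisibly.
#' @export
write_model_json <- function(m, path) {
  validate_model(m)
  doc <- list(
    id = m$id, namespace = m$namespace,
    biomass_reaction_id = m$biomass_reaction_id,
    metabolites = purrr::pmap(m$metabolites, function(id, name, compartment,
                                                      formula, charge, boundary) {
      out <- list(id = id, name = name, compartment = compartment)
      if (!is.na(formula)) out$formula <- formula
      if (!is.na(charge)) out$charge <- charge
      if (isTRUE(boundary)) out$boundary <- TRUE
      out
    }),
    reactions = purrr::pmap(m$reactions, function(id, name, stoichiometry,
                                                  lower_bound, upper_bound,
                                                  is_exchange, is_dissipation,
                                                  gene_rule) {
      out <- list(id = id, name = name, metabolites = as.list(stoichiometry),
                  lower_bound = lower_bound, upper_bound = upper_bound)
      if (!is.na(gene_rule)) out$gene_rule <- gene_rule
      out
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
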