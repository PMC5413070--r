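#' Default energy-dissipation reaction catalog
#'
#' One template per energy currency, fifteen in all: the NTPs (ATP, CTP, GTP,
#' UTP, ITP), the redox carriers (NADH, NADPH, FADH2, FMNH2, ubiquinol-8,
#' menaquinol-8, 2-demethylmenaquinol-8), acetyl-CoA, L-glutamate, and the
#' transmembrane proton gradient.  Each template discharges its currency
#' irreversibly, e.g. `atp + h2o -> adp + pi + h` for ATP.  The redox
#' templates are deliberately electron-unbalanced (`nadh -> nad + h` has no
#' electron acceptor): including the acceptor would let internal cofactor
#' regeneration re-capture the energy and the reaction could carry flux even
#' without a cycle.  The proton-gradient template `h[p] -> h[c]` discharges a
#' periplasm-to-cytosol gradient, falling back to the extracellular
#' compartment in two-compartment models.
#'
#' Equations are written over namespace-neutral species keys which
#' [build_dissipation_reactions()] resolves against the model through the
#' synonym table.  Users may supply their own catalog file with the same two
#' columns (`label`, `equation`).
#'
#' @param path optional path to a user catalog TSV; the default ships with
#'   the package.
#' @return A tibble with columns `label` and `equation`.
#' @export
dissipation_catalog <- function(path = NULL) {
  path <- path %||% system.file("extdata", "dissipation_catalog.tsv",
                                package = "egctools", mustWork = TRUE)
  cat_tbl <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  stopifnot(all(c("label", "equation") %in% names(cat_tbl)))
  cat_tbl
}

#' Metabolite synonym table for dissipation templates
#'
#' Maps each species key of the catalog to candidate base identifiers in the
#' BiGG, ModelSEED and MetaNetX namespaces (comma-separated).  These are
#' curated defaults; supply your own table to cover additional id variants.
#'
#' @param path optional path to a synonyms TSV (`species`, `namespace`,
#'   `ids`).
#' @return A tibble with columns `species`, `namespace`, `ids`.
#' @export
metabolite_synonyms <- function(path = NULL) {
  path <- path %||% system.file("extdata", "metabolite_synonyms.tsv",
                                package = "egctools", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

COMPARTMENT_CLASSES <- list(
  cytosol = c("c", "c0", "cytosol", "cytoplasm", "mnxc3", "in"),
  periplasm = c("p", "p0", "periplasm", "mnxc19"),
  extracellular = c("e", "e0", "extracellular", "mnxc2", "out", "ext"))

compartment_class <- function(comp) {
  comp <- tolower(comp)
  cls <- rep(NA_character_, length(comp))
  for (k in names(COMPARTMENT_CLASSES))
    cls[comp %in% COMPARTMENT_CLASSES[[k]]] <- k
  cls
}

## strip the compartment tag from a metabolite id given its compartment
strip_compartment <- function(id, comp) {
  pat <- paste0("(_|\\[|@)", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", comp),
                "\\]?$")
  vapply(seq_along(id),
         function(i) sub(pat[i], "", id[i], ignore.case = TRUE),
         character(1))
}

## resolve one species key against the model; returns a metabolite id or NA
resolve_species <- function(m, species, synonyms, class = NULL) {
  syn <- synonyms[synonyms$species == species &
                    synonyms$namespace == m$namespace, ]
  if (!nrow(syn)) return(NA_character_)
  bases <- tolower(trimws(unlist(strsplit(syn$ids, ","))))
  met_base <- tolower(strip_compartment(m$metabolites$id,
                                        m$metabolites$compartment))
  hit <- which(met_base %in% bases)
  if (!length(hit)) return(NA_character_)
  cls <- compartment_class(m$metabolites$compartment[hit])
  if (!is.null(class)) {
    hit2 <- hit[cls %in% class]
    if (!length(hit2)) return(NA_character_)
    return(m$metabolites$id[hit2[1]])
  }
  ## cytosol preferred when several compartments match
  ord <- order(match(cls, c("cytosol", "periplasm", "extracellular")),
               na.last = TRUE)
  m$metabolites$id[hit[ord][1]]
}

#' Build the energy-dissipation reactions for a model
#'
#' Resolves every catalog template against the model's metabolites (via the
#' namespace synonym table, preferring the cytosolic compartment) and scores
#' its integration: the fraction of the template's metabolites present in the
#' model.  A template with integration below 1 references a metabolite the
#' model lacks, so the assembled reaction could never carry flux; it is
#' returned flagged inactive and is not attached.
#'
#' The proton-gradient template requires a proton in the periplasm (falling
#' back to the extracellular compartment) and one in the cytosol.
#'
#' @param m a `metabolic_model`.
#' @param catalog a catalog tibble from [dissipation_catalog()].
#' @param synonyms a synonym tibble from [metabolite_synonyms()].
#' @return A tibble (one row per label) with columns `label`, `reaction_id`,
#'   `stoichiometry` (list of named numeric over resolved metabolite ids),
#'   `n_species`, `n_resolved`, `integration`, `active`, `unresolved` (list
#'   of unresolved species keys).
#' @export
build_dissipation_reactions <- function(m, catalog = dissipation_catalog(),
                                        synonyms = metabolite_synonyms()) {
  validate_model(m)
  purrr::map_dfr(seq_len(nrow(catalog)), function(i) {
    label <- catalog$label[i]
    eq <- parse_equation(catalog$equation[i])$stoichiometry
    keys <- names(eq)
    resolved <- vapply(keys, function(k) {
      if (grepl("\\[p\\]$", k)) {
        resolve_species(m, sub("\\[p\\]$", "", k), synonyms,
                        class = c("periplasm", "extracellular"))
      } else if (grepl("\\[c\\]$", k)) {
        resolve_species(m, sub("\\[c\\]$", "", k), synonyms,
                        class = "cytosol")
      } else {
        resolve_species(m, k, synonyms)
      }
    }, character(1))
    ## the two sides of the proton gradient must not collapse onto the same
    ## metabolite
    if (anyDuplicated(stats::na.omit(resolved)))
      resolved[duplicated(resolved, incomparables = NA)] <- NA_character_
    ok <- !is.na(resolved)
    st <- stats::setNames(unname(eq[ok]), resolved[ok])
    tibble::tibble(
      label = label,
      reaction_id = paste0("EDR_", label),
      stoichiometry = list(st),
      n_species = length(keys),
      n_resolved = sum(ok),
      integration = sum(ok) / length(keys),
      active = all(ok),
      unresolved = list(keys[!ok]))
  })
}

#' Attach dissipation reactions to a model
#'
#' Adds every active (fully integrated) dissipation reaction as an
#' irreversible reaction with bounds `[0, edr_upper]`, marked so the
#' detection clamp exempts it.  Attaching converts any energy-generating
#' cycle into a closed internal cycle whose flux the detection LP can
#' maximize.  A dissipation reaction alone cannot create a cycle: it strictly
#' consumes its energy metabolite, so an EGC-free model stays EGC-free.
#'
#' Attaching twice is refused with a warning (the model is returned
#' unchanged).  Id collisions with existing reactions are resolved by
#' suffixing and recorded in the `dissipation_aliases` attribute.
#'
#' @param m a `metabolic_model`.
#' @param drs tibble from [build_dissipation_reactions()].
#' @param edr_upper upper flux bound for dissipation reactions; they are
#'   exempt from the unit clamp applied to network reactions.
#' @return The augmented model, with the dissipation table stored in the
#'   `dissipation` attribute.
#' @export
attach_dissipation <- function(m, drs = build_dissipation_reactions(m),
                               edr_upper = 1000) {
  if (isTRUE(attr(m, "dissipation_attached"))) {
    warning("dissipation reactions already attached; returning model unchanged")
    return(m)
  }
  act <- drs[drs$active, , drop = FALSE]
  aliases <- character(0)
  ids <- act$reaction_id
  for (k in seq_along(ids)) {
    while (ids[k] %in% c(m$reactions$id, ids[-k])) {
      aliases[act$reaction_id[k]] <- paste0(ids[k], "_edr")
      ids[k] <- paste0(ids[k], "_edr")
    }
  }
  act$reaction_id <- ids
  if (nrow(act)) {
    new_rxns <- tibble::tibble(
      id = act$reaction_id,
      name = paste0("energy dissipation (", act$label, ")"),
      stoichiometry = act$stoichiometry,
      lower_bound = 0, upper_bound = edr_upper,
      is_exchange = FALSE, is_dissipation = TRUE,
      gene_rule = NA_character_)
    m$reactions <- dplyr::bind_rows(m$reactions, new_rxns)
  }
  drs$added_reaction_id <- ifelse(drs$active, act$reaction_id[
    match(drs$label, act$label)], NA_character_)
  validate_model(m)
  attr(m, "dissipation_attached") <- TRUE
  attr(m, "dissipation") <- drs
  if (length(aliases)) attr(m, "dissipation_aliases") <- aliases
  m
}

#' Detach previously attached dissipation reactions
#'
#' Inverse of [attach_dissipation()]: removes every reaction flagged as a
#' dissipation reaction and clears the bookkeeping attributes.
#'
#' @param m a `metabolic_model`.
#' @return The model without dissipation reactions.
#' @export
detach_dissipation <- function(m) {
  m$reactions <- m$reactions[!m$reactions$is_dissipation, , drop = FALSE]
  attr(m, "dissipation_attached") <- NULL
  attr(m, "dissipation") <- NULL
  attr(m, "dissipation_aliases") <- NULL
  m
}
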