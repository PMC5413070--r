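#' Construct a constraint-based metabolic model
#'
#' The central container of the package: a stoichiometric network with flux
#' bounds, compartment and namespace annotations, and a designated biomass
#' reaction.  Both component tables are tibbles, so models compose naturally
#' with dplyr verbs; the stoichiometry of each reaction is a named numeric
#' vector (negative coefficients for substrates, positive for products) held
#' in a list-column.
#'
#' @param metabolites a data frame with columns `id` and `compartment`
#'   (required) and optionally `name`, `formula`, `charge`, `boundary`.
#' @param reactions a data frame with columns `id` and `stoichiometry` (a list
#'   of named numeric vectors keyed by metabolite id) and optionally `name`,
#'   `lower_bound`, `upper_bound`, `gene_rule`, `is_exchange`,
#'   `is_dissipation`.  Missing bounds default to `[-1000, 1000]`.
#' @param biomass_reaction_id id of the biomass (growth) reaction.
#' @param namespace metabolite identifier namespace, one of `"bigg"`,
#'   `"modelseed"`, `"metanetx"`.
#' @param id model identifier used in reports.
#'
#' @return An object of class `metabolic_model`.
#' @seealso [read_model_sbml()], [read_model_json()], [make_fixture()]
#' @examples
#' m <- metabolic_model(
#'   metabolites = tibble::tibble(id = c("a_c", "b_c"), compartment = "c"),
#'   reactions = tibble::tibble(
#'     id = c("EX_a", "CONV", "BIO"),
#'     stoichiometry = list(c(a_c = -1), c(a_c = -1, b_c = 1), c(b_c = -1)),
#'     lower_bound = c(-10, 0, 0), upper_bound = c(0, 1000, 1000)),
#'   biomass_reaction_id = "BIO", namespace = "bigg")
#' m
#' @export
metabolic_model <- function(metabolites, reactions, biomass_reaction_id,
                            namespace = c("bigg", "modelseed", "metanetx"),
                            id = "model") {
  namespace <- match.arg(namespace)
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"formula" %in% names(metabolites)) metabolites$formula <- NA_character_
  if (!"charge" %in% names(metabolites)) metabolites$charge <- NA_real_
  if (!"boundary" %in% names(metabolites)) metabolites$boundary <- FALSE
  metabolites <- metabolites[, c("id", "name", "compartment", "formula",
                                 "charge", "boundary")]
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"lower_bound" %in% names(reactions)) reactions$lower_bound <- -1000
  if (!"upper_bound" %in% names(reactions)) reactions$upper_bound <- 1000
  if (!"gene_rule" %in% names(reactions)) reactions$gene_rule <- NA_character_
  if (!"is_dissipation" %in% names(reactions)) reactions$is_dissipation <- FALSE
  reactions$is_exchange <- flag_exchanges(reactions, metabolites) &
    reactions$id != biomass_reaction_id
  reactions <- reactions[, c("id", "name", "stoichiometry", "lower_bound",
                             "upper_bound", "is_exchange", "is_dissipation",
                             "gene_rule")]
  m <- structure(
    list(metabolites = metabolites, reactions = reactions,
         biomass_reaction_id = biomass_reaction_id, namespace = namespace,
         id = id),
    class = "metabolic_model")
  validate_model(m)
  m
}

## A reaction is an exchange when it touches exactly one non-boundary
## metabolite: the universal single-metabolite boundary convention.
flag_exchanges <- function(reactions, metabolites) {
  boundary_ids <- metabolites$id[isTRUE_vec(metabolites$boundary)]
  vapply(reactions$stoichiometry, function(s) {
    length(setdiff(names(s), boundary_ids)) == 1L
  }, logical(1)) & !reactions$is_dissipation
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Validate a metabolic model
#'
#' Checks referential integrity (every stoichiometry key resolves to a
#' declared metabolite), bound sanity, id uniqueness, non-empty compartments
#' and the presence of the biomass reaction.  Called by all constructors;
#' exposed for models assembled by hand.
#'
#' @param m a `metabolic_model`.
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_model <- function(m) {
  stopifnot(inherits(m, "metabolic_model"))
  mets <- m$metabolites; rxns <- m$reactions
  if (anyDuplicated(mets$id))
    stop("duplicated metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  if (anyDuplicated(rxns$id))
    stop("duplicated reaction ids: ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  if (any(!nzchar(mets$compartment) | is.na(mets$compartment)))
    stop("every metabolite needs a non-empty compartment")
  if (any(lengths(rxns$stoichiometry) == 0L))
    stop("empty stoichiometry in reaction(s): ",
         paste(rxns$id[lengths(rxns$stoichiometry) == 0L], collapse = ", "))
  dangling <- setdiff(unique(unlist(lapply(rxns$stoichiometry, names))), mets$id)
  if (length(dangling))
    stop("stoichiometry references undeclared metabolite(s): ",
         paste(dangling, collapse = ", "))
  bad <- rxns$lower_bound > rxns$upper_bound + 1e-12
  if (any(bad))
    stop("lower bound exceeds upper bound for: ",
         paste(rxns$id[bad], collapse = ", "))
  if (!m$biomass_reaction_id %in% rxns$id)
    stop("biomass reaction '", m$biomass_reaction_id, "' not in the model")
  invisible(m)
}

#' Stoichiometric matrix of a model
#'
#' @param m a `metabolic_model`.
#' @return A sparse `Matrix` (metabolites x reactions) with dimnames, the `S`
#'   of the steady-state condition `S v = 0`.
#' @export
stoich_matrix <- function(m) {
  mets <- m$metabolites$id
  rxns <- m$reactions$id
  trip <- purrr::imap(m$reactions$stoichiometry, function(s, j) {
    cbind(match(names(s), mets), j, unname(s))
  })
  trip <- do.call(rbind, trip)
  Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                       dims = c(length(mets), length(rxns)),
                       dimnames = list(mets, rxns))
}

#' Parse a reaction equation string
#'
#' Accepts the conventional arrow notation used throughout metabolic
#' modelling, e.g. `"atp_c + h2o_c -> adp_c + pi_c + h_c"` or
#' `"2 h_e <=> 2 h_c"`.  Coefficients default to 1; `<=>`/`<->` marks the
#' reaction reversible.
#'
#' @param equation a single equation string.
#' @return A list with `stoichiometry` (named numeric, substrates negative)
#'   and `reversible` (logical).
#' @examples
#' parse_equation("atp_c + h2o_c -> adp_c + pi_c + h_c")
#' @export
parse_equation <- function(equation) {
  stopifnot(is.character(equation), length(equation) == 1L)
  rev_arrow <- grepl("<->|<=>", equation)
  sides <- strsplit(equation, "<->|<=>|-->|->|=>", perl = TRUE)[[1]]
  if (length(sides) > 2L) stop("malformed equation: ", equation)
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    terms <- trimws(strsplit(side, "\\s\\+\\s|^\\+\\s|\\s\\+$", perl = TRUE)[[1]])
    terms <- terms[nzchar(terms)]
    out <- numeric(0)
    for (t in terms) {
      mm <- regmatches(t, regexec("^([0-9]*\\.?[0-9]+)\\s+(.*)$", t))[[1]]
      if (length(mm) == 3L) {
        out[mm[3]] <- sign * as.numeric(mm[2]) + (out[mm[3]] %||% 0)
      } else {
        out[t] <- sign + (out[t] %||% 0)
      }
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- c(lhs, rhs)
  ## merge duplicated species across sides
  st <- tapply(st, names(st), sum)
  st <- stats::setNames(as.numeric(st), names(st))
  st <- st[st != 0]
  list(stoichiometry = st, reversible = rev_arrow)
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L || (length(a) == 1L && is.na(a))) b else a
}

#' Build a reaction table from equation strings
#'
#' Convenience used by the fixture generators and tests: turns a tibble with
#' `id` and `equation` columns into the reaction table expected by
#' [metabolic_model()].  Bounds default to `[0, 1000]` for irreversible and
#' `[-1000, 1000]` for reversible equations unless given explicitly.
#'
#' @param tbl data frame with columns `id`, `equation` and optionally
#'   `lower_bound`, `upper_bound`, `name`, `gene_rule`.
#' @return A tibble suitable as the `reactions` argument of
#'   [metabolic_model()].
#' @export
reactions_from_equations <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  parsed <- lapply(tbl$equation, parse_equation)
  tbl$stoichiometry <- lapply(parsed, `[[`, "stoichiometry")
  reversible <- vapply(parsed, `[[`, logical(1), "reversible")
  if (!"lower_bound" %in% names(tbl)) tbl$lower_bound <- NA_real_
  if (!"upper_bound" %in% names(tbl)) tbl$upper_bound <- NA_real_
  tbl$lower_bound <- ifelse(is.na(tbl$lower_bound),
                            ifelse(reversible, -1000, 0), tbl$lower_bound)
  tbl$upper_bound <- ifelse(is.na(tbl$upper_bound), 1000, tbl$upper_bound)
  tbl$equation <- NULL
  tbl
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, " [", x$namespace, "]\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      "   reactions: ", nrow(x$reactions),
      " (", sum(x$reactions$is_exchange), " exchange, ",
      sum(x$reactions$is_dissipation), " dissipation)\n", sep = "")
  cat("  biomass: ", x$biomass_reaction_id, "\n", sep = "")
  if (isTRUE(attr(x, "normalized"))) cat("  normalized\n")
  invisible(x)
}

## internal accessors ------------------------------------------------------

reaction_index <- function(m, id) {
  i <- match(id, m$reactions$id)
  if (anyNA(i)) stop("unknown reaction id(s): ",
                     paste(id[is.na(i)], collapse = ", "))
  i
}

#' Constrain reaction directions to zero
#'
#' Applies a set of unidirectional deactivations by clamping the affected
#' bound to zero.  Reactions are never deleted, so a curator can re-enable
#' them in conditions where they are thermodynamically feasible.
#'
#' @param m a `metabolic_model`.
#' @param removals a data frame with columns `reaction_id` and `direction`
#'   (`"forward"` or `"backward"`).
#' @return The constrained model.
#' @export
apply_removals <- function(m, removals) {
  if (is.null(removals) || nrow(removals) == 0L) return(m)
  for (k in seq_len(nrow(removals))) {
    i <- reaction_index(m, removals$reaction_id[k])
    if (removals$direction[k] == "forward") {
      m$reactions$upper_bound[i] <- min(m$reactions$upper_bound[i], 0)
    } else {
      m$reactions$lower_bound[i] <- max(m$reactions$lower_bound[i], 0)
    }
  }
  m
}
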