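#' Normalize a model for cycle analysis
#'
#' Brings a loaded model into the conventions assumed by the detection and
#' correction routines:
#'
#' * every exchange reaction is written in the secretion direction (the
#'   metabolite is a substrate, so positive flux exports and negative flux
#'   takes up) — reactions written the other way round are sign-flipped along
#'   with their bounds, which relabels but does not change the feasible flux
#'   polytope;
#' * the non-growth-associated ATP maintenance reaction (ATPM), identified by
#'   per-namespace id/name patterns, has its lower bound relaxed to zero, so
#'   no obligatory ATP regeneration is imposed while exchanges are closed.
#'
#' Every altered bound or flipped reaction is recorded in a change log
#' retrievable with [normalization_log()].  The operation is idempotent.
#'
#' @param m a `metabolic_model`.
#' @param atpm_patterns character vector of regular expressions matched
#'   (case-insensitively) against reaction ids and names to locate the ATP
#'   maintenance reaction.
#' @return The normalized model, with attributes `normalized` and
#'   `normalization_log`.
#' @export
normalize_model <- function(m,
                            atpm_patterns = c("^ATPM$", "^rxn00062",
                                              "maintenance")) {
  validate_model(m)
  log <- list()
  rx <- m$reactions
  for (i in which(rx$is_exchange)) {
    st <- rx$stoichiometry[[i]]
    boundary_ids <- m$metabolites$id[isTRUE_vec(m$metabolites$boundary)]
    key <- setdiff(names(st), boundary_ids)
    if (st[[key]] > 0) {
      log[[length(log) + 1L]] <- tibble::tibble(
        reaction_id = rx$id[i], change = "exchange_flip",
        old = sprintf("[%g, %g], coef %+g", rx$lower_bound[i],
                      rx$upper_bound[i], st[[key]]),
        new = sprintf("[%g, %g], coef %+g", -rx$upper_bound[i],
                      -rx$lower_bound[i], -st[[key]]))
      rx$stoichiometry[[i]] <- -st
      lbu <- c(-rx$upper_bound[i], -rx$lower_bound[i])
      rx$lower_bound[i] <- lbu[1]
      rx$upper_bound[i] <- lbu[2]
    }
  }
  pat <- paste(atpm_patterns, collapse = "|")
  atpm <- which((grepl(pat, rx$id, ignore.case = TRUE) |
                   grepl(pat, rx$name %|na|% "", ignore.case = TRUE)) &
                  !rx$is_exchange & !rx$is_dissipation)
  if (!length(atpm)) {
    log[[length(log) + 1L]] <- tibble::tibble(
      reaction_id = NA_character_, change = "atpm_not_found",
      old = NA_character_, new = NA_character_)
  } else {
    for (i in atpm) {
      if (rx$lower_bound[i] > 0) {
        log[[length(log) + 1L]] <- tibble::tibble(
          reaction_id = rx$id[i], change = "atpm_lower_bound",
          old = format(rx$lower_bound[i]), new = "0")
        rx$lower_bound[i] <- 0
      }
    }
  }
  m$reactions <- rx
  attr(m, "normalized") <- TRUE
  attr(m, "normalization_log") <-
    dplyr::bind_rows(log) %||% tibble::tibble(reaction_id = character(0),
                                              change = character(0),
                                              old = character(0),
                                              new = character(0))
  m
}

#' Retrieve the normalization change log
#'
#' @param m a model returned by [normalize_model()].
#' @return A tibble with one row per recorded change (`exchange_flip`,
#'   `atpm_lower_bound`, or an `atpm_not_found` marker).  Idempotent re-runs
#'   log nothing but the marker when no ATPM exists.
#' @export
normalization_log <- function(m) {
  lg <- attr(m, "normalization_log")
  if (is.null(lg)) stop("model has not been normalized")
  lg
}

#' Open all exchange reactions to a rich medium
#'
#' Sets every exchange reaction's bounds to `[-uptake, uptake]`, the
#' "maximally rich environment" used by the viability filter and the growth
#' case of the correction program.  1000 flux units is the de-facto
#' unbounded convention of published reconstructions.
#'
#' @param m a `metabolic_model`.
#' @param uptake uptake magnitude (flux units).
#' @return The model with opened exchanges.
#' @export
open_exchanges <- function(m, uptake = 1000) {
  ex <- m$reactions$is_exchange
  m$reactions$lower_bound[ex] <- -uptake
  m$reactions$upper_bound[ex] <- uptake
  m
}

#' Close all exchange reactions
#'
#' Fixes every exchange flux to zero — the "no influx" condition under which
#' any dissipation flux betrays an energy-generating cycle.
#'
#' @param m a `metabolic_model`.
#' @return The model with all exchanges fixed to zero flux.
#' @export
close_exchanges <- function(m) {
  ex <- m$reactions$is_exchange
  m$reactions$lower_bound[ex] <- 0
  m$reactions$upper_bound[ex] <- 0
  m
}

## maximize the flux of one reaction under S v = 0 and the current bounds
fba_optimum <- function(m, objective_id = m$biomass_reaction_id,
                        maximize = TRUE) {
  S <- as.matrix(stoich_matrix(m))
  n <- ncol(S)
  obj <- numeric(n)
  obj[reaction_index(m, objective_id)] <- 1
  res <- lp_solve(obj, S, rep("=", nrow(S)), rep(0, nrow(S)),
                  lb = m$reactions$lower_bound, ub = m$reactions$upper_bound,
                  maximize = maximize)
  if (res$status != "optimal")
    stop("LP solver failure in flux-balance problem: status ", res$status)
  list(objective = res$objective,
       flux = stats::setNames(res$x, m$reactions$id), status = res$status)
}

#' Test whether a model can produce biomass on rich medium
#'
#' Opens every exchange to `[-uptake, uptake]` and maximizes the biomass
#' reaction by linear programming.  Models failing this filter are excluded
#' from cycle correction, since the growth case of the bi-level program would
#' be vacuous.
#'
#' @param m a normalized `metabolic_model`.
#' @param threshold minimal biomass flux regarded as viable.
#' @param uptake rich-medium uptake magnitude.
#' @return A one-row tibble with columns `viable`, `optimum`, `threshold`,
#'   `status`.
#' @export
check_viability <- function(m, threshold = 1e-6, uptake = 1000) {
  res <- fba_optimum(open_exchanges(m, uptake))
  tibble::tibble(viable = res$objective >= threshold,
                 optimum = res$objective,
                 threshold = threshold, status = res$status)
}

#' Screen reactions for elemental and charge imbalance
#'
#' Computes, for every internal reaction, the per-element difference between
#' products and substrates from the metabolite chemical formulas, and the
#' charge difference where charges are annotated.  Exchange and dissipation
#' reactions are exempt (the former are unbalanced by design, the latter
#' deliberately omit the electron acceptor).  Mass- or electron-unbalanced
#' reactions can themselves induce spurious energy generation, so models
#' should be balanced before cycles are interpreted; this screen only flags,
#' it never repairs.
#'
#' @param m a `metabolic_model`.
#' @param tol per-element tolerance on the absolute delta.
#' @return A tibble with columns `reaction_id`, `element_deltas` (list of
#'   named numeric), `charge_delta`, `balanced`, `status` (`"ok"`,
#'   `"skipped: no formula"`, or `"skipped: unparseable formula"`).
#' @export
check_balance <- function(m, tol = 1e-6) {
  validate_model(m)
  formulas <- stats::setNames(m$metabolites$formula, m$metabolites$id)
  charges <- stats::setNames(m$metabolites$charge, m$metabolites$id)
  rows <- lapply(seq_len(nrow(m$reactions)), function(i) {
    r <- m$reactions[i, ]
    base <- tibble::tibble(reaction_id = r$id, element_deltas = list(NULL),
                           charge_delta = NA_real_, balanced = NA,
                           status = "ok")
    if (r$is_exchange || r$is_dissipation) {
      base$status <- "exempt"
      return(base)
    }
    st <- r$stoichiometry[[1]]
    fs <- formulas[names(st)]
    if (any(is.na(fs) | !nzchar(fs))) {
      base$status <- "skipped: no formula"
      return(base)
    }
    parsed <- lapply(fs, parse_formula)
    if (any(vapply(parsed, is.null, logical(1)))) {
      bad <- names(st)[vapply(parsed, is.null, logical(1))]
      warning("unparseable formula for metabolite(s) ",
              paste(bad, collapse = ", "), " in reaction ", r$id)
      base$status <- "skipped: unparseable formula"
      return(base)
    }
    elements <- unique(unlist(lapply(parsed, names)))
    delta <- stats::setNames(numeric(length(elements)), elements)
    for (k in seq_along(st)) {
      f <- parsed[[k]]
      delta[names(f)] <- delta[names(f)] + st[[k]] * f
    }
    ch <- charges[names(st)]
    charge_delta <- if (any(is.na(ch))) NA_real_ else sum(st * ch)
    balanced <- all(abs(delta) <= tol) &&
      (is.na(charge_delta) || abs(charge_delta) <= tol)
    base$element_deltas <- list(delta[abs(delta) > tol])
    base$charge_delta <- charge_delta
    base$balanced <- balanced
    base
  })
  dplyr::bind_rows(rows)
}

## "C10H12N5O13P3" -> c(C = 10, H = 12, N = 5, O = 13, P = 3); NULL if the
## string contains anything but element tokens
parse_formula <- function(f) {
  if (is.na(f) || !nzchar(f)) return(NULL)
  tokens <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", f)[[1]]
  parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", f))[[1]]
  if (sum(nchar(parts)) != nchar(f)) return(NULL)
  el <- sub("[0-9.]*$", "", parts)
  ct <- sub("^[A-Za-z]*", "", parts)
  ct <- ifelse(nzchar(ct), as.numeric(ct), 1)
  out <- tapply(ct, el, sum)
  stats::setNames(as.numeric(out), names(out))
}
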