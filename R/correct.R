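#' Settings for cycle correction
#'
#' @param tg growth threshold of the growth case.  With `tg_mode =
#'   "relative"` (default) it is a fraction of the unmodified model's
#'   rich-medium biomass optimum; with `"absolute"` it is a flux value.
#' @param tg_mode `"relative"` or `"absolute"`.
#' @param clamp unit clamp applied to network fluxes in the non-growth case,
#'   matching detection; keeps the inner problem's duals small.
#' @param big_M bound on the dual variables gated by the removal binaries.
#'   The post-hoc certificate re-runs detection on every returned solution,
#'   so a too-small value is caught rather than silently accepted.
#' @param uptake rich-medium uptake magnitude for the growth case.
#' @param zero_tolerance tolerance under which a dissipation optimum counts
#'   as zero during certification.
#' @param deterministic add a tiny index-ordered perturbation to the removal
#'   weights so ties between equally minimal removal sets break
#'   reproducibly (smallest candidate indices win).
#' @param node_limit branch-and-bound node cap.
#' @return A list of class `correction_settings`.
#' @export
correction_settings <- function(tg = 0.01, tg_mode = c("relative", "absolute"),
                                clamp = 1, big_M = 1000, uptake = 1000,
                                zero_tolerance = 1e-6, deterministic = TRUE,
                                node_limit = 100000L) {
  structure(list(tg = tg, tg_mode = match.arg(tg_mode), clamp = clamp,
                 big_M = big_M, uptake = uptake,
                 zero_tolerance = zero_tolerance,
                 deterministic = deterministic, node_limit = node_limit),
            class = "correction_settings")
}

#' Patterns identifying the ATP synthase reaction
#'
#' Default id/name patterns used when the correction is asked to retain the
#' ATP synthase: removing it does eliminate most ATP-charging cycles, but
#' also abolishes respiration, so a second, synthase-protected search is the
#' recommended protocol.
#' @return Character vector of regular expressions.
#' @export
atp_synthase_patterns <- function() {
  c("^ATPS\\d*r?(pp)?$", "^rxn08173", "^rxn10042", "atp synthase", "F[o0]F1")
}

#' Split reactions into unidirectional removal candidates
#'
#' Reversible reactions are treated as two independent unidirectional
#' reactions: one forward candidate per reaction with a positive upper bound
#' and one backward candidate per reaction with a negative lower bound.
#' Exchange and dissipation reactions are never candidates; the biomass
#' reaction is protected by default; additional protection patterns are
#' matched against reaction ids and names.  Protected candidates are listed
#' but carry `protected = TRUE` and their removal binaries are fixed to zero.
#'
#' @param m a normalized `metabolic_model` with dissipation attached.
#' @param protect character vector of regular expressions (matched
#'   case-insensitively against ids and names) for reactions that must stay
#'   active in both directions.
#' @param protect_biomass protect the biomass reaction (default `TRUE`).
#' @param weights optional data frame (`reaction_id`, optional `direction`,
#'   `weight`) of removal weights; default weight is 1 for every candidate
#'   (all removals equally likely).  Differential weights let a curator
#'   penalize, e.g., removal of irreversible reactions or of reactions with
#'   strong thermodynamic support.
#' @return A tibble with columns `reaction_id`, `direction`, `weight`,
#'   `protected`.
#' @export
split_reversibles <- function(m, protect = character(0),
                              protect_biomass = TRUE, weights = NULL) {
  rx <- m$reactions
  internal <- !rx$is_exchange & !rx$is_dissipation
  pat <- protect
  if (protect_biomass)
    pat <- c(pat, paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                                   m$biomass_reaction_id), "$"))
  prot_rxn <- rep(FALSE, nrow(rx))
  if (length(pat)) {
    hits <- rep(FALSE, nrow(rx))
    for (p in pat)
      hits <- hits | grepl(p, rx$id, ignore.case = TRUE) |
        grepl(p, rx$name %|na|% "", ignore.case = TRUE)
    if (length(protect) && !any(
      vapply(protect, function(p)
        any(grepl(p, rx$id[internal], ignore.case = TRUE) |
              grepl(p, (rx$name %|na|% "")[internal], ignore.case = TRUE)),
        logical(1))))
      warning("protection pattern(s) matched no reaction: ",
              paste(protect, collapse = ", "))
    prot_rxn <- hits
  }
  fw <- which(internal & rx$upper_bound > 0)
  bw <- which(internal & rx$lower_bound < 0)
  cand <- dplyr::bind_rows(
    tibble::tibble(reaction_id = rx$id[fw], direction = "forward",
                   protected = prot_rxn[fw]),
    tibble::tibble(reaction_id = rx$id[bw], direction = "backward",
                   protected = prot_rxn[bw]))
  cand <- dplyr::arrange(cand, match(.data$reaction_id, rx$id),
                         dplyr::desc(.data$direction == "forward"))
  cand$weight <- 1
  if (!is.null(weights)) {
    weights <- tibble::as_tibble(weights)
    for (i in seq_len(nrow(weights))) {
      sel <- cand$reaction_id == weights$reaction_id[i]
      if ("direction" %in% names(weights) && !is.na(weights$direction[i]))
        sel <- sel & cand$direction == weights$direction[i]
      cand$weight[sel] <- weights$weight[i]
    }
  }
  cand[, c("reaction_id", "direction", "weight", "protected")]
}

#' Assemble the single-level removal program
#'
#' Encodes the bi-level search for a minimum-weight set of unidirectional
#' reaction deactivations as one mixed-integer program.  The outer objective
#' minimizes the weighted sum of removal binaries.  The growth case keeps
#' the constrained model able to produce biomass at least `T_g` on rich
#' medium; the non-growth case demands that, with all exchanges closed, the
#' maximal summed dissipation flux is exactly zero.  That inner maximization
#' is replaced by the existence of a feasible point of its dual with
#' objective at most zero (weak duality then pins the inner optimum at
#' zero, and zero flux makes it attained).  Because every non-growth bound
#' constant is one-signed, each dual-objective term is nonnegative and the
#' binary-dual products reduce to big-M gating constraints: a bound's dual
#' may only be positive where the corresponding direction has been removed.
#'
#' Both cases share one binary per candidate direction.  Candidates never
#' include exchanges or dissipation reactions; protected candidates carry no
#' binary (fixed to zero).
#'
#' @param m a normalized, viability-checked model with dissipation attached.
#' @param candidates candidate table from [split_reversibles()].
#' @param settings a [correction_settings()] object.
#' @return A `bilevel_program` object (variable table, constraint triplets,
#'   candidate map, growth threshold) accepted by [solve_correction()],
#'   [enumerate_alternatives()] and [bilevel_feasible()].
#' @export
build_bilevel <- function(m, candidates, settings = correction_settings()) {
  if (!isTRUE(attr(m, "dissipation_attached")))
    stop("attach dissipation reactions first (attach_dissipation)")
  rx <- m$reactions
  n <- nrow(rx)
  mg <- open_exchanges(m, settings$uptake)
  lbg <- mg$reactions$lower_bound
  ubg <- mg$reactions$upper_bound
  biomass_before <- fba_optimum(mg)$objective
  T_g <- if (settings$tg_mode == "relative")
    settings$tg * biomass_before else settings$tg
  if (T_g > biomass_before + 1e-9)
    stop("configuration error: growth threshold ", format(T_g),
         " exceeds the unmodified rich-medium biomass optimum ",
         format(biomass_before))

  nb <- detection_bounds(m, settings$clamp)
  ng_idx <- which(!rx$is_exchange)          # non-growth keeps these columns
  lbn <- nb$lb[ng_idx]
  ubn <- nb$ub[ng_idx]
  S <- as.matrix(stoich_matrix(m))
  nm <- nrow(S)
  nng <- length(ng_idx)
  cvec <- as.numeric(rx$is_dissipation[ng_idx])

  free_cand <- candidates[!candidates$protected, , drop = FALSE]
  nc <- nrow(free_cand)
  cand_rxn <- match(free_cand$reaction_id, rx$id)
  cand_ng <- match(cand_rxn, ng_idx)        # NA never occurs (internal only)

  ## variable layout: [delta | v_g | v_ng | mu | alpha | beta]
  id_delta <- seq_len(nc)
  id_vg <- nc + seq_len(n)
  id_vng <- nc + n + seq_len(nng)
  id_mu <- nc + n + nng + seq_len(nm)
  id_alpha <- nc + n + nng + nm + seq_len(nng)
  id_beta <- nc + n + nng + nm + nng + seq_len(nng)
  N <- nc + n + 2 * nng + nm + nng

  M <- settings$big_M
  lb <- c(rep(0, nc), lbg, lbn, rep(-M, nm), rep(0, nng), rep(0, nng))
  ub <- c(rep(1, nc), ubg, ubn, rep(M, nm), rep(M, nng), rep(M, nng))
  ## a bound's dual must vanish unless that direction is removable:
  ## non-candidate directions get alpha/beta fixed to zero
  alpha_gated <- rep(FALSE, nng)
  beta_gated <- rep(FALSE, nng)
  alpha_gated[cand_ng[free_cand$direction == "forward"]] <- TRUE
  beta_gated[cand_ng[free_cand$direction == "backward"]] <- TRUE
  ub[id_alpha][!alpha_gated & ubn > 0] <- 0
  ub[id_beta][!beta_gated & lbn < 0] <- 0

  tri_i <- integer(0); tri_j <- integer(0); tri_x <- numeric(0)
  dirs <- character(0); rhs <- numeric(0)
  nrow_cur <- 0L
  add_row <- function(j, x, d, r) {
    nrow_cur <<- nrow_cur + 1L
    tri_i <<- c(tri_i, rep(nrow_cur, length(j)))
    tri_j <<- c(tri_j, j)
    tri_x <<- c(tri_x, x)
    dirs <<- c(dirs, d)
    rhs <<- c(rhs, r)
  }

  ## growth case steady state: S v_g = 0
  for (i in seq_len(nm)) {
    nz <- which(S[i, ] != 0)
    add_row(id_vg[nz], S[i, nz], "=", 0)
  }
  ## biomass threshold
  add_row(id_vg[reaction_index(m, m$biomass_reaction_id)], 1, ">=", T_g)
  ## non-growth steady state: S_ng v_ng = 0
  for (i in seq_len(nm)) {
    nz <- which(S[i, ng_idx] != 0)
    if (length(nz)) add_row(id_vng[nz], S[i, ng_idx[nz]], "=", 0)
  }
  ## dual feasibility: S_ng' mu + alpha - beta = c
  for (k in seq_len(nng)) {
    col <- S[, ng_idx[k]]
    nz <- which(col != 0)
    add_row(c(id_mu[nz], id_alpha[k], id_beta[k]), c(col[nz], 1, -1),
            "=", cvec[k])
  }
  ## binary gating
  for (k in seq_len(nc)) {
    y <- cand_rxn[k]; yn <- cand_ng[k]
    if (free_cand$direction[k] == "forward") {
      if (ubg[y] > 0) add_row(c(id_vg[y], id_delta[k]), c(1, ubg[y]),
                              "<=", ubg[y])
      if (ubn[yn] > 0) add_row(c(id_vng[yn], id_delta[k]), c(1, ubn[yn]),
                               "<=", ubn[yn])
      add_row(c(id_alpha[yn], id_delta[k]), c(1, -M), "<=", 0)
    } else {
      if (lbg[y] < 0) add_row(c(id_vg[y], id_delta[k]), c(1, lbg[y]),
                              ">=", lbg[y])
      if (lbn[yn] < 0) add_row(c(id_vng[yn], id_delta[k]), c(1, lbn[yn]),
                               ">=", lbn[yn])
      add_row(c(id_beta[yn], id_delta[k]), c(1, -M), "<=", 0)
    }
  }

  A <- matrix(0, nrow_cur, N)
  A[cbind(tri_i, tri_j)] <- tri_x
  obj <- numeric(N)
  obj[id_delta] <- free_cand$weight
  if (settings$deterministic && nc > 0)
    obj[id_delta] <- obj[id_delta] + 1e-6 * seq_len(nc)

  structure(list(model = m, candidates = candidates, free_cand = free_cand,
                 A = A, dir = dirs, rhs = rhs, lb = lb, ub = ub, obj = obj,
                 id_delta = id_delta, id_vg = id_vg, id_vng = id_vng,
                 T_g = T_g, biomass_before = biomass_before,
                 settings = settings),
            class = "bilevel_program")
}

#' @export
print.bilevel_program <- function(x, ...) {
  cat("<bilevel_program> model ", x$model$id, "\n",
      "  binaries: ", length(x$id_delta),
      "  variables: ", length(x$lb),
      "  constraints: ", nrow(x$A), "\n",
      "  growth threshold T_g = ", format(x$T_g, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Continuous feasibility of the program at a fixed binary assignment
#'
#' Fixes the removal binaries to `delta` and tests whether the remaining
#' (continuous) constraint system is feasible.  Used to validate the
#' single-level reformulation against directly solving the two underlying
#' linear programs for every assignment.
#'
#' @param p a `bilevel_program`.
#' @param delta 0/1 vector, one entry per unprotected candidate.
#' @return `TRUE` if feasible.
#' @export
bilevel_feasible <- function(p, delta) {
  stopifnot(length(delta) == length(p$id_delta))
  lb <- p$lb; ub <- p$ub
  lb[p$id_delta] <- delta
  ub[p$id_delta] <- delta
  res <- lp_solve(numeric(length(lb)), p$A, p$dir, p$rhs, lb, ub)
  res$status == "optimal"
}

## certify a removal set with the two plain LPs (detection + growth)
certify_removals <- function(m, removals, T_g, settings) {
  m2 <- apply_removals(m, removals)
  rep2 <- suppressWarnings(detect_egc(
    m2, detection_settings(settings$clamp, settings$zero_tolerance)))
  egc_free <- !any(rep2$has_egc) &&
    attr(rep2, "aggregate_optimum") <= settings$zero_tolerance
  after <- fba_optimum(open_exchanges(m2, settings$uptake))$objective
  list(egc_free = egc_free, biomass_after = after,
       growth_ok = after >= T_g - 1e-9, report = rep2)
}

new_removal_solution <- function(removals, objective, p, cert, status,
                                 alternatives = NULL) {
  structure(list(removals = removals, objective = objective,
                 biomass_before = p$biomass_before,
                 biomass_after = cert$biomass_after %||% NA_real_,
                 certified_egc_free = isTRUE(cert$egc_free),
                 growth_ok = isTRUE(cert$growth_ok),
                 T_g = p$T_g, status = status, alternatives = alternatives,
                 model_id = p$model$id),
            class = "removal_solution")
}

#' Solve the removal program
#'
#' Runs branch and bound on the assembled program and returns a
#' minimum-weight set of unidirectional deactivations.  Every returned
#' solution is independently re-certified by plain linear programming:
#' detection is re-solved on the constrained model (all dissipation optima
#' must vanish) and the rich-medium growth LP must clear the threshold.
#' This guards the duality reformulation (e.g. a big-M chosen too small)
#' rather than trusting the MILP's own feasibility.  Removals constrain
#' bounds to zero; nothing is deleted.
#'
#' @param p a `bilevel_program` from [build_bilevel()].
#' @return A `removal_solution` with elements `removals` (tibble of
#'   `reaction_id`, `direction`, `weight`), `objective` (weighted removal
#'   count), `biomass_before`/`biomass_after` (rich medium),
#'   `certified_egc_free`, `growth_ok`, `status`.  If no removal-only
#'   correction exists the status is `"no_removal_correction"` and the
#'   removal set is empty.
#' @export
solve_correction <- function(p) {
  stopifnot(inherits(p, "bilevel_program"))
  res <- milp_solve(p$obj, p$A, p$dir, p$rhs, p$lb, p$ub,
                    int_vars = p$id_delta, maximize = FALSE,
                    node_limit = p$settings$node_limit)
  if (res$status == "infeasible") {
    sol <- new_removal_solution(
      p$free_cand[0, c("reaction_id", "direction", "weight")], NA_real_, p,
      list(egc_free = FALSE, biomass_after = NA_real_, growth_ok = FALSE),
      "no_removal_correction")
    return(sol)
  }
  chosen <- which(round(res$x[p$id_delta]) == 1)
  removals <- p$free_cand[chosen, c("reaction_id", "direction", "weight")]
  cert <- certify_removals(p$model, removals, p$T_g, p$settings)
  status <- if (res$status == "optimal") "optimal" else "incumbent"
  if (!cert$egc_free || !cert$growth_ok)
    warning("certificate failed for model ", p$model$id,
            ": egc_free=", cert$egc_free, ", growth_ok=", cert$growth_ok,
            " (consider increasing big_M)")
  new_removal_solution(removals, sum(removals$weight), p, cert, status)
}

#' @export
print.removal_solution <- function(x, ...) {
  cat("<removal_solution> model ", x$model_id, " [", x$status, "]\n", sep = "")
  if (nrow(x$removals)) {
    cat("  removals (weighted objective ", format(x$objective), "):\n",
        sep = "")
    cat(paste0("    - ", x$removals$reaction_id, " (",
               x$removals$direction, ")\n"), sep = "")
  } else cat("  no removals\n")
  cat("  biomass before/after: ", format(x$biomass_before, digits = 6), " / ",
      format(x$biomass_after, digits = 6),
      "  (threshold ", format(x$T_g, digits = 6), ")\n", sep = "")
  cat("  certified cycle-free: ", x$certified_egc_free, "\n", sep = "")
  invisible(x)
}

#' Enumerate alternative optimal removal sets
#'
#' Repeatedly re-solves the program with the objective pinned to the optimal
#' value and a no-good cut excluding each previously returned binary
#' pattern, yielding up to `k` distinct equally minimal removal sets —
#' alternatives a curator can choose between.
#'
#' @param p a `bilevel_program`.
#' @param k maximum number of solutions.
#' @return A list of `removal_solution` objects (possibly shorter than `k`).
#' @export
enumerate_alternatives <- function(p, k = 5L) {
  first <- solve_correction(p)
  if (first$status != "optimal" || k < 1L) return(list(first)[seq_len(min(1, k))])
  out <- list(first)
  zstar <- first$objective
  A <- p$A; dirs <- p$dir; rhs <- p$rhs
  w <- numeric(length(p$lb)); w[p$id_delta] <- p$free_cand$weight
  A <- rbind(A, w); dirs <- c(dirs, "<="); rhs <- c(rhs, zstar + 1e-6)
  while (length(out) < k) {
    prev <- out[[length(out)]]$removals
    sel <- p$id_delta[p$free_cand$reaction_id %in% prev$reaction_id &
                        paste(p$free_cand$reaction_id,
                              p$free_cand$direction) %in%
                        paste(prev$reaction_id, prev$direction)]
    cut <- numeric(length(p$lb)); cut[sel] <- 1
    A <- rbind(A, cut); dirs <- c(dirs, "<="); rhs <- c(rhs, nrow(prev) - 1)
    res <- milp_solve(p$obj, A, dirs, rhs, p$lb, p$ub,
                      int_vars = p$id_delta, maximize = FALSE,
                      node_limit = p$settings$node_limit)
    if (res$status != "optimal") break
    chosen <- which(round(res$x[p$id_delta]) == 1)
    removals <- p$free_cand[chosen, c("reaction_id", "direction", "weight")]
    if (sum(removals$weight) > zstar + 1e-6) break
    cert <- certify_removals(p$model, removals, p$T_g, p$settings)
    out[[length(out) + 1L]] <-
      new_removal_solution(removals, sum(removals$weight), p, cert, "optimal")
  }
  out
}

#' Two-pass correction protocol
#'
#' Pass one searches with no protections ("simple").  Because the cheapest
#' fix frequently removes the ATP synthase — eliminating most ATP-charging
#' cycles but also the model's capacity for respiratory ATP production —
#' pass two repeats the search with the ATP synthase (or a user-supplied
#' protected set) forced to stay active ("synthase").  Both solutions are
#' returned for side-by-side reporting.
#'
#' @param m a normalized model with dissipation attached.
#' @param settings a [correction_settings()].
#' @param synthase_patterns patterns identifying the reactions to retain in
#'   pass two; defaults to [atp_synthase_patterns()].
#' @param weights optional weight table, see [split_reversibles()].
#' @return A list with elements `simple` and `synthase`, each a
#'   `removal_solution`.  If no reaction matches the synthase patterns the
#'   second pass equals the first and a warning is issued.
#' @export
run_two_pass <- function(m, settings = correction_settings(),
                         synthase_patterns = atp_synthase_patterns(),
                         weights = NULL) {
  cand1 <- split_reversibles(m, weights = weights)
  p1 <- build_bilevel(m, cand1, settings)
  simple <- solve_correction(p1)
  pat <- paste(synthase_patterns, collapse = "|")
  has_synthase <- any((grepl(pat, m$reactions$id, ignore.case = TRUE) |
                         grepl(pat, m$reactions$name %|na|% "",
                               ignore.case = TRUE)) &
                        !m$reactions$is_exchange & !m$reactions$is_dissipation)
  if (!has_synthase) {
    warning("no ATP synthase match in model ", m$id,
            "; synthase pass identical to the simple pass")
    return(list(simple = simple, synthase = simple))
  }
  cand2 <- suppressWarnings(
    split_reversibles(m, protect = synthase_patterns, weights = weights))
  p2 <- build_bilevel(m, cand2, settings)
  list(simple = simple, synthase = solve_correction(p2))
}

#' Biomass impact of a correction
#'
#' Ratio of the rich-medium biomass optimum after applying the removals to
#' the optimum before — the quantity whose distribution shows how strongly
#' spurious energy inflates growth predictions (reductions beyond 25% are
#' typical for automatically built models).
#'
#' @param m the model the solution was computed for.
#' @param sol a `removal_solution`.
#' @param uptake rich-medium uptake magnitude.
#' @return A single ratio in `[0, 1]`; `NA` with a warning if the model
#'   produced no biomass to begin with.
#' @export
biomass_impact <- function(m, sol, uptake = 1000) {
  before <- fba_optimum(open_exchanges(m, uptake))$objective
  if (before <= 1e-9) {
    warning("biomass optimum is zero before correction; ratio undefined")
    return(NA_real_)
  }
  after <- fba_optimum(open_exchanges(apply_removals(m, sol$removals),
                                      uptake))$objective
  after / before
}
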