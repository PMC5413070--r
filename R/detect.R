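#' Settings for energy-generating cycle detection
#'
#' @param clamp magnitude of the flux clamp applied to every network reaction
#'   other than the dissipation reactions: reversible reactions are bounded
#'   to `[-clamp, clamp]`, irreversible ones to `[0, clamp]` (intersected
#'   with their own bounds).  Cycles tend to run at maximal flux, so with
#'   `clamp = 1` the optimal dissipation flux is a lower bound on the number
#'   of non-overlapping cycles for the tested currency.
#' @param zero_tolerance optima at or below this value count as zero; optima
#'   in `(0, zero_tolerance]` are reported as `"numerically zero"` with a
#'   warning, since LP solvers return noise at the 1e-9 scale.
#' @return A list of class `detection_settings`.
#' @export
detection_settings <- function(clamp = 1, zero_tolerance = 1e-6) {
  stopifnot(clamp > 0, zero_tolerance >= 0)
  structure(list(clamp = clamp, zero_tolerance = zero_tolerance),
            class = "detection_settings")
}

## detection-mode bounds: exchanges closed, network reactions clipped into
## [-clamp, clamp], dissipation reactions untouched
detection_bounds <- function(m, clamp) {
  lb <- m$reactions$lower_bound
  ub <- m$reactions$upper_bound
  net <- !m$reactions$is_exchange & !m$reactions$is_dissipation
  lb[net] <- pmin(pmax(lb[net], -clamp), clamp)
  ub[net] <- pmin(pmax(ub[net], -clamp), clamp)
  ex <- m$reactions$is_exchange
  lb[ex] <- 0
  ub[ex] <- 0
  list(lb = lb, ub = ub)
}

#' Detect energy-generating cycles
#'
#' For each attached dissipation reaction `d`, solves the linear program
#'
#'   maximize v_d  subject to  S v = 0,  v_i = 0 for every exchange i,
#'   network fluxes clamped to `[-clamp, clamp]` / `[0, clamp]`,
#'
#' i.e. asks how much of the energy currency the network can dissipate at
#' steady state with no nutrient influx whatsoever.  A strictly positive
#' optimum certifies at least one energy-generating cycle for that currency.
#' Zero flux is always feasible, so every optimum is nonnegative; templates
#' that could not be fully integrated are reported with status
#' `"not integrated"` and no cycle.  An aggregate pre-screen maximizing the
#' summed dissipation flux is solved as well and stored as an attribute.
#'
#' @param m a normalized `metabolic_model` with dissipation reactions
#'   attached (see [normalize_model()], [attach_dissipation()]).
#' @param settings a [detection_settings()] object.
#' @return An `egc_report`: a tibble with one row per catalog label and
#'   columns `label`, `reaction_id`, `integration`, `optimum`, `has_egc`,
#'   `status`, plus attributes `model_id`, `aggregate_optimum`, `clamp` and
#'   `zero_tolerance`.
#' @examples
#' m <- make_fixture("fig6d")$model
#' m <- attach_dissipation(normalize_model(m))
#' detect_egc(m)
#' @export
detect_egc <- function(m, settings = detection_settings()) {
  if (!isTRUE(attr(m, "dissipation_attached")))
    stop("attach dissipation reactions first (attach_dissipation)")
  if (!isTRUE(attr(m, "normalized")))
    warning("model has not been normalized; ATPM lower bound and exchange ",
            "directions are taken as-is")
  drs <- attr(m, "dissipation")
  bounds <- detection_bounds(m, settings$clamp)
  S <- as.matrix(stoich_matrix(m))
  ndir <- rep("=", nrow(S))
  zero <- rep(0, nrow(S))
  solve_target <- function(rid) {
    obj <- numeric(ncol(S))
    obj[reaction_index(m, rid)] <- 1
    res <- lp_solve(obj, S, ndir, zero, bounds$lb, bounds$ub, maximize = TRUE)
    if (res$status != "optimal")
      stop("internal error: detection LP returned status ", res$status,
           " (zero flux is always feasible and the clamp bounds the optimum)")
    res
  }
  rows <- purrr::map_dfr(seq_len(nrow(drs)), function(i) {
    if (!drs$active[i]) {
      return(tibble::tibble(label = drs$label[i],
                            reaction_id = NA_character_,
                            integration = drs$integration[i],
                            optimum = NA_real_, has_egc = FALSE,
                            status = "not integrated"))
    }
    res <- solve_target(drs$added_reaction_id[i])
    opt <- max(res$objective, 0)
    status <- "optimal"
    if (opt > 0 && opt <= settings$zero_tolerance) {
      warning("optimum for ", drs$label[i], " (", format(opt),
              ") is numerically zero at tolerance ",
              format(settings$zero_tolerance))
      status <- "numerically zero"
    }
    tibble::tibble(label = drs$label[i],
                   reaction_id = drs$added_reaction_id[i],
                   integration = drs$integration[i],
                   optimum = opt,
                   has_egc = opt > settings$zero_tolerance,
                   status = status)
  })
  ## aggregate pre-screen: maximize the summed dissipation flux
  obj <- numeric(ncol(S))
  obj[m$reactions$is_dissipation] <- 1
  agg <- if (any(obj > 0)) {
    res <- lp_solve(obj, S, ndir, zero, bounds$lb, bounds$ub, maximize = TRUE)
    max(res$objective, 0)
  } else 0
  structure(rows,
            class = c("egc_report", class(rows)),
            model_id = m$id, aggregate_optimum = agg,
            clamp = settings$clamp, zero_tolerance = settings$zero_tolerance)
}

#' @export
print.egc_report <- function(x, ...) {
  cat("<egc_report> model ", attr(x, "model_id"),
      " - aggregate dissipation optimum ",
      format(attr(x, "aggregate_optimum"), digits = 6), "\n", sep = "")
  NextMethod()
}

#' Lower bound on the number of non-overlapping cycles
#'
#' With all network fluxes clamped to unit magnitude, one unit of dissipation
#' flux requires a full cycle's worth of reactions, so the detection optimum
#' bounds from below the number of non-overlapping cycles for the tested
#' currency.  The bound is reported as-is: a cycle whose stoichiometry yields
#' fractional energy per turn (e.g. a 4-protons-per-ATP synthase) produces an
#' optimum below 1 even though one cycle exists, so the value is not floored.
#'
#' @param report an `egc_report` computed with `clamp = 1`.
#' @param target a catalog label present in the report.
#' @return The optimum for `target`, a lower bound on its number of
#'   non-overlapping cycles.
#' @export
count_lower_bound <- function(report, target) {
  if (!isTRUE(all.equal(attr(report, "clamp"), 1)))
    stop("the cycle-count bound requires unit clamps (report computed with ",
         "clamp = ", attr(report, "clamp"), ")")
  i <- match(target, report$label)
  if (is.na(i)) stop("unknown target label: ", target)
  if (is.na(report$optimum[i])) return(0)
  report$optimum[i]
}

#' Extract one minimal cycle carrying a dissipation flux
#'
#' Re-solves the detection LP for one currency, then minimizes the flux
#' 1-norm at the fixed optimum, and returns the support (reactions with
#' non-zero flux) of the resulting vertex solution — the candidate cycle to
#' show a curator.
#'
#' @param m a model with dissipation attached.
#' @param target catalog label with a detected cycle.
#' @param settings a [detection_settings()].
#' @return Character vector of reaction ids (including the dissipation
#'   reaction).
#' @export
enumerate_cycle_support <- function(m, target,
                                    settings = detection_settings()) {
  if (!isTRUE(attr(m, "dissipation_attached")))
    stop("attach dissipation reactions first (attach_dissipation)")
  drs <- attr(m, "dissipation")
  i <- match(target, drs$label)
  if (is.na(i)) stop("unknown target label: ", target)
  if (!drs$active[i]) stop("target ", target, " is not integrated; no cycle")
  rid <- drs$added_reaction_id[i]
  bounds <- detection_bounds(m, settings$clamp)
  S <- as.matrix(stoich_matrix(m))
  n <- ncol(S)
  obj <- numeric(n)
  d <- reaction_index(m, rid)
  obj[d] <- 1
  res <- lp_solve(obj, S, rep("=", nrow(S)), rep(0, nrow(S)),
                  bounds$lb, bounds$ub, maximize = TRUE)
  vstar <- max(res$objective, 0)
  if (vstar <= settings$zero_tolerance)
    stop("no energy-generating cycle detected for target ", target)
  ## minimize sum(t), t >= |v|, with the dissipation flux fixed at its optimum
  lb <- c(bounds$lb, rep(0, n))
  ub <- c(bounds$ub, pmax(abs(bounds$lb), abs(bounds$ub)))
  lb[d] <- vstar; ub[d] <- vstar
  A1 <- cbind(S, matrix(0, nrow(S), n))
  A2 <- cbind(diag(n), -diag(n))      #  v - t <= 0
  A3 <- cbind(-diag(n), -diag(n))     # -v - t <= 0
  A <- rbind(A1, A2, A3)
  dirs <- c(rep("=", nrow(S)), rep("<=", 2 * n))
  rhs <- rep(0, nrow(A))
  objn <- c(numeric(n), rep(1, n))
  res2 <- lp_solve(objn, A, dirs, rhs, lb, ub, maximize = FALSE)
  if (res2$status != "optimal")
    stop("internal error: support LP returned status ", res2$status)
  v <- res2$x[seq_len(n)]
  m$reactions$id[abs(v) > settings$zero_tolerance]
}
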