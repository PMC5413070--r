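# Independent oracles used to validate the package's LP/MILP implementations.
# They deliberately avoid the package's solver: cycle existence is decided by
# nullspace enumeration over reaction subsets (every elementary mode has a
# nullity-one support), and LP optima are cross-checked with boot::simplex.

# cache fixtures prepared once per test run
.fixture_cache <- new.env(parent = emptyenv())
prep_fixture <- function(name) {
  if (!is.null(.fixture_cache[[name]])) return(.fixture_cache[[name]])
  fx <- make_fixture(name)
  md <- attach_dissipation(normalize_model(fx$model))
  out <- list(model = md, spec = fx$spec)
  .fixture_cache[[name]] <- out
  out
}

cycle_fixture_names <- c("fig2", "fig6a", "fig6b", "fig6c", "fig6d",
                         "two_pathway_biomass", "disjoint_double_fig6d",
                         "synthase_trap")
all_fixture_names <- c(cycle_fixture_names, "viable_control")

# Existence of a steady-state flux with positive dissipation flux for
# `label`, decided by enumerating reaction subsets: a subset is a candidate
# cycle support iff the restricted stoichiometric matrix has nullity one and
# its nullspace vector respects every direction restriction with positive
# flux through the dissipation reaction.  Exchanges are excluded (closed).
oracle_has_egc <- function(md, label, tol = 1e-9, max_universe = 12) {
  rx <- md$reactions
  drs <- attr(md, "dissipation")
  i <- match(label, drs$label)
  if (is.na(i) || !drs$active[i]) return(FALSE)
  did <- drs$added_reaction_id[i]
  uni <- which(!rx$is_exchange)
  stopifnot(length(uni) <= max_universe)
  S <- as.matrix(stoich_matrix(md))
  d <- match(did, rx$id)
  others <- setdiff(uni, d)
  fwd_only <- rx$lower_bound >= 0
  bwd_only <- rx$upper_bound <= 0
  sign_ok <- function(w, subset) {
    all(w[fwd_only[subset]] >= -tol) && all(w[bwd_only[subset]] <= tol) &&
      w[which(subset == d)] > tol
  }
  n_others <- length(others)
  for (mask in 0:(2^n_others - 1)) {
    subset <- c(d, others[bitwAnd(mask, 2^(seq_len(n_others) - 1)) > 0])
    B <- S[, subset, drop = FALSE]
    sv <- svd(B, nu = 0)
    null_dim <- sum(sv$d < 1e-8) + max(0, ncol(B) - length(sv$d))
    if (null_dim != 1L) next
    v <- sv$v[, ncol(B)]
    if (sign_ok(v, subset) || sign_ok(-v, subset)) return(TRUE)
  }
  FALSE
}

# detection-mode bounds derived independently of the package internals
oracle_detection_bounds <- function(md, clamp = 1) {
  lb <- md$reactions$lower_bound
  ub <- md$reactions$upper_bound
  net <- !md$reactions$is_exchange & !md$reactions$is_dissipation
  lb[net] <- pmin(pmax(lb[net], -clamp), clamp)
  ub[net] <- pmin(pmax(ub[net], -clamp), clamp)
  lb[md$reactions$is_exchange] <- 0
  ub[md$reactions$is_exchange] <- 0
  list(lb = lb, ub = ub)
}

# LP via boot::simplex (shift to nonnegative variables, upper bounds as rows)
boot_lp_max <- function(obj, Aeq, beq, lb, ub) {
  stopifnot(requireNamespace("boot", quietly = TRUE))
  keep <- (ub - lb) > 1e-12
  beq2 <- as.numeric(beq - Aeq %*% lb)
  A <- Aeq[, keep, drop = FALSE]
  d <- (ub - lb)[keep]
  o <- obj[keep]
  zero_row <- apply(abs(A), 1, max) < 1e-12
  stopifnot(all(abs(beq2[zero_row]) < 1e-9))
  A <- A[!zero_row, , drop = FALSE]
  beq2 <- beq2[!zero_row]
  neg <- beq2 < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  beq2[neg] <- -beq2[neg]
  res <- boot::simplex(a = o, A1 = diag(length(o)), b1 = d,
                       A3 = A, b3 = beq2, maxi = TRUE)
  stopifnot(res$solved == 1)
  res$value + sum(obj * lb)
}

boot_detect_optimum <- function(md, label) {
  drs <- attr(md, "dissipation")
  i <- match(label, drs$label)
  if (!drs$active[i]) return(NA_real_)
  b <- oracle_detection_bounds(md)
  S <- as.matrix(stoich_matrix(md))
  obj <- numeric(ncol(S))
  obj[match(drs$added_reaction_id[i], md$reactions$id)] <- 1
  boot_lp_max(obj, S, rep(0, nrow(S)), b$lb, b$ub)
}

# direct two-LP check of a removal set: no residual dissipation flux
# (aggregate detection LP) and biomass above threshold on rich medium
direct_removals_ok <- function(md, removals, T_g, tol = 1e-6) {
  m2 <- apply_removals(md, removals)
  b <- oracle_detection_bounds(m2)
  S <- as.matrix(stoich_matrix(m2))
  obj <- as.numeric(m2$reactions$is_dissipation)
  agg <- lp_solve(obj, S, rep("=", nrow(S)), rep(0, nrow(S)), b$lb, b$ub,
                  maximize = TRUE)$objective
  growth <- open_exchanges(m2) |> (\(mm) {
    o <- numeric(nrow(mm$reactions))
    o[match(mm$biomass_reaction_id, mm$reactions$id)] <- 1
    Sm <- as.matrix(stoich_matrix(mm))
    lp_solve(o, Sm, rep("=", nrow(Sm)), rep(0, nrow(Sm)),
             mm$reactions$lower_bound, mm$reactions$upper_bound)$objective
  })()
  (agg <= tol) && (growth >= T_g - 1e-9)
}

# exhaustive minimal-cut search over candidate directions, by growing size
oracle_min_cuts <- function(md, candidates, T_g, max_size = 4) {
  free <- candidates[!candidates$protected, , drop = FALSE]
  n <- nrow(free)
  for (size in 0:max_size) {
    sets <- if (size == 0) list(integer(0))
            else utils::combn(n, size, simplify = FALSE)
    hits <- Filter(function(idx) direct_removals_ok(md, free[idx, ], T_g),
                   sets)
    if (length(hits))
      return(list(size = size,
                  cuts = lapply(hits, function(idx)
                    paste(free$reaction_id[idx], free$direction[idx]))))
  }
  list(size = NA_integer_, cuts = list())
}
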