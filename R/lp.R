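#' Solve a dense linear program
#'
#' A self-contained two-phase primal simplex over dense tableaus, supporting
#' general row constraints (`<=`, `=`, `>=`) and finite box bounds on the
#' variables.  All flux-balance, detection and certification programs in the
#' package go through this routine; problem sizes are those of curated toy
#' networks and reduced genome-scale instances (hundreds of variables), for
#' which a dense tableau is entirely adequate.
#'
#' Variables with `lb == ub` are substituted out before solving; finite upper
#' bounds are handled as explicit rows after shifting each variable to its
#' lower bound.  Dantzig pricing is used with an automatic switch to Bland's
#' rule when the objective stalls, which guarantees termination on degenerate
#' vertices (flux-balance polytopes are highly degenerate).
#'
#' @param obj numeric objective coefficients (length `n`).
#' @param mat constraint matrix (`m` x `n`), or `NULL` for box-only problems.
#' @param dir character vector of row senses, each one of `"<="`, `"="`, `">="`.
#' @param rhs numeric right-hand sides (length `m`).
#' @param lb,ub numeric bounds (length `n`); `lb` must be finite, `ub` may be
#'   `Inf`.
#' @param maximize logical; maximize (default) or minimize `obj`.
#' @param tol pivot tolerance.
#' @param feas_tol feasibility tolerance used to declare phase-1 success.
#' @param max_iter simplex iteration cap across both phases.
#'
#' @return A list with elements `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"` or `"iteration_limit"`), `objective`, `x` (the primal
#'   solution, a vertex of the feasible polytope when optimal) and
#'   `iterations`.
#' @examples
#' # max x + y s.t. x + 2y <= 4, x <= 3, 0 <= x, y
#' lp_solve(c(1, 1), rbind(c(1, 2)), "<=", 4, lb = c(0, 0), ub = c(3, Inf))
#' @export
lp_solve <- function(obj, mat = NULL, dir = NULL, rhs = NULL, lb, ub,
                     maximize = TRUE, tol = 1e-9, feas_tol = 1e-7,
                     max_iter = 20000L) {
  n <- length(obj)
  if (is.null(mat)) {
    mat <- matrix(0, 0, n)
    dir <- character(0)
    rhs <- numeric(0)
  }
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  stopifnot(ncol(mat) == n, length(dir) == nrow(mat), length(rhs) == nrow(mat),
            length(lb) == n, length(ub) == n, all(is.finite(lb)),
            all(lb <= ub + 1e-12))
  if (!all(dir %in% c("<=", "=", ">=")))
    stop("row senses must be one of '<=', '=', '>='")

  sense <- if (maximize) 1 else -1
  c0 <- sense * obj

  ## substitute out fixed variables
  fixed <- (ub - lb) <= 1e-12
  x_full <- numeric(n)
  x_full[fixed] <- lb[fixed]
  keep <- which(!fixed)
  if (length(keep) == 0L) {
    resid <- rhs - as.numeric(mat %*% x_full)
    ok <- all((dir == "<=" & resid >= -feas_tol) |
                (dir == ">=" & resid <= feas_tol) |
                (dir == "=" & abs(resid) <= feas_tol))
    return(list(status = if (ok) "optimal" else "infeasible",
                objective = sum(obj * x_full), x = x_full, iterations = 0L))
  }
  A <- mat[, keep, drop = FALSE]
  b <- rhs - as.numeric(mat[, fixed, drop = FALSE] %*% lb[fixed])
  cc <- c0[keep]
  l <- lb[keep]
  u <- ub[keep]

  ## shift to y = x - l >= 0
  b <- b - as.numeric(A %*% l)
  d <- u - l                      # upper bounds on y, possibly Inf
  nb <- length(keep)

  ## append rows y_j <= d_j for finite d
  ubi <- which(is.finite(d))
  if (length(ubi)) {
    Aub <- matrix(0, length(ubi), nb)
    Aub[cbind(seq_along(ubi), ubi)] <- 1
    A <- rbind(A, Aub)
    b <- c(b, d[ubi])
    dir <- c(dir, rep("<=", length(ubi)))
  }
  m <- nrow(A)

  ## make rhs nonnegative
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    dir[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[neg]]
  }

  ## slacks, surplus, artificials
  n_slack <- sum(dir == "<=")
  n_surp <- sum(dir == ">=")
  n_art <- sum(dir != "<=")
  N <- nb + n_slack + n_surp + n_art
  Tab <- matrix(0, m, N + 1L)
  Tab[, seq_len(nb)] <- A
  Tab[, N + 1L] <- b
  basis <- integer(m)
  si <- nb; pi_ <- nb + n_slack; ai <- nb + n_slack + n_surp
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      si <- si + 1L; Tab[i, si] <- 1; basis[i] <- si
    } else if (dir[i] == ">=") {
      pi_ <- pi_ + 1L; Tab[i, pi_] <- -1
      ai <- ai + 1L; Tab[i, ai] <- 1; basis[i] <- ai
    } else {
      ai <- ai + 1L; Tab[i, ai] <- 1; basis[i] <- ai
    }
  }
  art_cols <- seq.int(nb + n_slack + n_surp + 1L, length.out = n_art)
  iters <- 0L

  run_phase <- function(Tab, basis, cost, allowed, max_iter) {
    ## maximize cost over columns in `allowed`; returns updated state
    m <- nrow(Tab); rhs_col <- ncol(Tab)
    red <- cost - as.numeric(crossprod(cost[basis], Tab[, -rhs_col, drop = FALSE]))
    red[!allowed] <- -Inf
    objval <- sum(cost[basis] * Tab[, rhs_col])
    it <- 0L; stall <- 0L; bland <- FALSE
    repeat {
      if (it >= max_iter) return(list(Tab = Tab, basis = basis, status = "iteration_limit", it = it))
      cand <- which(red > tol)
      if (!length(cand)) return(list(Tab = Tab, basis = basis, status = "optimal", it = it))
      q <- if (bland) cand[1L] else cand[which.max(red[cand])]
      col <- Tab[, q]
      pos <- which(col > tol)
      if (!length(pos)) return(list(Tab = Tab, basis = basis, status = "unbounded", it = it))
      ratio <- Tab[pos, rhs_col] / col[pos]
      rmin <- min(ratio)
      ties <- pos[ratio <= rmin + tol]
      p <- if (length(ties) > 1L) ties[which.min(basis[ties])] else ties
      ## pivot on (p, q)
      piv <- Tab[p, q]
      Tab[p, ] <- Tab[p, ] / piv
      other <- setdiff(seq_len(m), p)
      if (length(other)) {
        f <- Tab[other, q]
        nz <- which(abs(f) > 0)
        if (length(nz))
          Tab[other[nz], ] <- Tab[other[nz], , drop = FALSE] -
            outer(f[nz], Tab[p, ])
      }
      red_new <- red - red[q] * Tab[p, -rhs_col]
      red_new[q] <- 0
      red <- red_new
      red[!allowed] <- -Inf
      basis[p] <- q
      newobj <- sum(cost[basis] * Tab[, rhs_col])
      if (newobj > objval + tol) { stall <- 0L } else { stall <- stall + 1L }
      objval <- newobj
      if (stall > 200L) bland <- TRUE
      it <- it + 1L
    }
  }

  allowed <- rep(TRUE, N)
  if (n_art > 0L) {
    cost1 <- numeric(N)
    cost1[art_cols] <- -1
    ph1 <- run_phase(Tab, basis, cost1, allowed, max_iter)
    iters <- iters + ph1$it
    Tab <- ph1$Tab; basis <- ph1$basis
    if (ph1$status == "iteration_limit")
      return(list(status = "iteration_limit", objective = NA_real_,
                  x = NULL, iterations = iters))
    ph1_obj <- sum(cost1[basis] * Tab[, N + 1L])
    if (ph1_obj < -feas_tol)
      return(list(status = "infeasible", objective = NA_real_,
                  x = NULL, iterations = iters))
    ## drive remaining artificials out of the basis
    drop_rows <- integer(0)
    for (i in which(basis %in% art_cols)) {
      row <- Tab[i, seq_len(nb + n_slack + n_surp)]
      j <- which(abs(row) > tol)[1L]
      if (is.na(j)) { drop_rows <- c(drop_rows, i); next }
      piv <- Tab[i, j]
      Tab[i, ] <- Tab[i, ] / piv
      other <- setdiff(seq_len(nrow(Tab)), i)
      f <- Tab[other, j]
      nz <- which(abs(f) > 0)
      if (length(nz))
        Tab[other[nz], ] <- Tab[other[nz], , drop = FALSE] - outer(f[nz], Tab[i, ])
      basis[i] <- j
    }
    if (length(drop_rows)) {
      Tab <- Tab[-drop_rows, , drop = FALSE]
      basis <- basis[-drop_rows]
    }
    allowed[art_cols] <- FALSE
  }

  cost2 <- numeric(N)
  cost2[seq_len(nb)] <- cc
  ph2 <- run_phase(Tab, basis, cost2, allowed, max_iter - iters)
  iters <- iters + ph2$it
  if (ph2$status %in% c("unbounded", "iteration_limit"))
    return(list(status = ph2$status, objective = NA_real_, x = NULL,
                iterations = iters))
  Tab <- ph2$Tab; basis <- ph2$basis
  y <- numeric(N)
  y[basis] <- Tab[, ncol(Tab)]
  x_full[keep] <- y[seq_len(nb)] + l
  list(status = "optimal", objective = sum(obj * x_full), x = x_full,
       iterations = iters)
}

#' Solve a mixed-integer linear program by branch and bound
#'
#' Depth-first branch and bound over [lp_solve()] relaxations.  Intended for
#' the removal-set programs of this package, where the integer variables are
#' a modest number of binary deactivation indicators; the zero branch is
#' explored first, which quickly produces small incumbent removal sets.
#'
#' @inheritParams lp_solve
#' @param int_vars integer indices of variables required to take integer
#'   values (binaries in all internal uses).
#' @param int_tol integrality tolerance.
#' @param node_limit maximum number of branch-and-bound nodes.
#'
#' @return A list with `status` (`"optimal"`, `"infeasible"` or
#'   `"node_limit"`), `objective`, `x` and `nodes`.  With `"node_limit"` the
#'   incumbent (best integer-feasible point found) is returned and flagged
#'   non-optimal.
#' @export
milp_solve <- function(obj, mat = NULL, dir = NULL, rhs = NULL, lb, ub,
                       int_vars = integer(0), maximize = FALSE,
                       int_tol = 1e-6, node_limit = 100000L, ...) {
  sense <- if (maximize) -1 else 1        # work in minimization
  cmin <- sense * obj
  best <- list(objective = Inf, x = NULL)
  stack <- list(list(lb = lb, ub = ub))
  nodes <- 0L
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > node_limit) {
      return(list(status = "node_limit",
                  objective = if (is.null(best$x)) NA_real_ else sense * best$objective,
                  x = best$x, nodes = nodes))
    }
    rel <- lp_solve(cmin, mat, dir, rhs, node$lb, node$ub, maximize = FALSE, ...)
    if (rel$status != "optimal") next
    if (rel$objective >= best$objective - 1e-9) next
    xi <- rel$x[int_vars]
    frac <- abs(xi - round(xi))
    if (!length(frac) || max(frac) <= int_tol) {
      x <- rel$x
      x[int_vars] <- round(xi)
      best <- list(objective = rel$objective, x = x)
      next
    }
    j <- int_vars[which.max(frac)]
    lo <- node; hi <- node
    lo$ub[j] <- floor(rel$x[j])
    hi$lb[j] <- ceiling(rel$x[j])
    ## LIFO: push the "up" branch first so the "down" (zero) branch pops first
    stack[[length(stack) + 1L]] <- hi
    stack[[length(stack) + 1L]] <- lo
  }
  if (is.null(best$x))
    return(list(status = "infeasible", objective = NA_real_, x = NULL,
                nodes = nodes))
  list(status = "optimal", objective = sense * best$objective, x = best$x,
       nodes = nodes)
}
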