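# The simplex and branch-and-bound underpin every other module, so they are
# validated against an independent solver (boot::simplex) and against
# exhaustive enumeration before anything else relies on them.

test_that("lp_solve matches hand-solved reference problems", {
  # max x + y, x + 2y <= 4, 0 <= x <= 3, y >= 0: vertex (3, 0.5)
  r <- lp_solve(c(1, 1), rbind(c(1, 2)), "<=", 4, lb = c(0, 0), ub = c(3, Inf))
  expect_equal(r$status, "optimal")
  expect_equal(r$objective, 3.5)
  expect_equal(r$x, c(3, 0.5))

  # equalities with negative bounds: x = y, z = x + y, |x|,|y| <= 1 -> z* = 2
  r <- lp_solve(c(0, 0, 1), rbind(c(1, 1, -1), c(1, -1, 0)), c("=", "="),
                c(0, 0), lb = c(-1, -1, 0), ub = c(1, 1, 1000))
  expect_equal(r$objective, 2)

  # minimization with >= rows
  r <- lp_solve(c(1, 1), rbind(c(1, 1)), ">=", 2, lb = c(0, 0),
                ub = c(5, 5), maximize = FALSE)
  expect_equal(r$objective, 2)

  # infeasible: x >= 5 and x <= 2
  r <- lp_solve(1, rbind(1, 1), c(">=", "<="), c(5, 2), lb = 0, ub = 10)
  expect_equal(r$status, "infeasible")

  # fixed variables are substituted out
  r <- lp_solve(c(1, 1), rbind(c(1, 1)), "<=", 5, lb = c(2, 0), ub = c(2, 10))
  expect_equal(r$objective, 5)
  expect_equal(r$x[1], 2)
})

test_that("lp_solve agrees with boot::simplex on random inequality programs", {
  skip_if_not_installed("boot")
  set.seed(421)
  checked <- 0L
  for (t in 1:40) {
    n <- sample(3:8, 1); m <- sample(2:6, 1)
    A <- matrix(round(rnorm(m * n), 2), m, n)
    b <- round(runif(m, 1, 5), 2)
    a <- round(rnorm(n), 2)
    ref <- try(boot::simplex(a = a, A1 = A, b1 = b, maxi = TRUE),
               silent = TRUE)
    if (inherits(ref, "try-error") || ref$solved != 1) next
    got <- lp_solve(a, A, rep("<=", m), b, lb = rep(0, n),
                    ub = rep(1e7, n), maximize = TRUE)
    expect_equal(got$status, "optimal")
    expect_equal(got$objective, unname(ref$value), tolerance = 1e-7)
    checked <- checked + 1L
  }
  expect_gte(checked, 10L)
})

test_that("milp_solve equals exhaustive enumeration on random binary programs", {
  set.seed(77)
  for (t in 1:25) {
    n <- sample(3:8, 1); m <- sample(2:5, 1)
    A <- matrix(rbinom(m * n, 1, 0.5), m, n)
    A[cbind(seq_len(m), sample.int(n, m, replace = TRUE))] <- 1
    w <- round(runif(n, 0.5, 3), 2)
    res <- milp_solve(w, A, rep(">=", m), rep(1, m), lb = rep(0, n),
                      ub = rep(1, n), int_vars = seq_len(n),
                      maximize = FALSE)
    ## brute force over all assignments
    best <- Inf
    for (mask in 0:(2^n - 1)) {
      x <- as.numeric(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      if (all(A %*% x >= 1)) best <- min(best, sum(w * x))
    }
    if (is.infinite(best)) {
      expect_equal(res$status, "infeasible")
    } else {
      expect_equal(res$status, "optimal")
      expect_equal(res$objective, best, tolerance = 1e-9)
    }
  }
})

test_that("milp_solve reports infeasibility and respects fixed binaries", {
  # x1 + x2 >= 3 with binaries is infeasible
  r <- milp_solve(c(1, 1), rbind(c(1, 1)), ">=", 3, lb = c(0, 0),
                  ub = c(1, 1), int_vars = 1:2)
  expect_equal(r$status, "infeasible")
  # fixing a binary via its bounds constrains the solution
  r <- milp_solve(c(1, 2), rbind(c(1, 1)), ">=", 1, lb = c(0, 0),
                  ub = c(0, 1), int_vars = 1:2)
  expect_equal(r$objective, 2)
  expect_equal(round(r$x), c(0, 1))
})
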