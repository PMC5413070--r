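test_that("reversible splitting yields one candidate per usable direction", {
  md <- prep_fixture("fig6a")$model
  cand <- split_reversibles(md)
  # reversible transporters contribute two candidates, irreversible one
  expect_equal(sum(cand$reaction_id == "MALt2"), 2L)
  expect_equal(sum(cand$reaction_id == "GLCt"), 1L)
  expect_equal(cand$direction[cand$reaction_id == "GLCt"], "forward")
  # exchanges and dissipation reactions are never candidates
  expect_false(any(cand$reaction_id %in%
                     md$reactions$id[md$reactions$is_exchange |
                                       md$reactions$is_dissipation]))
  # biomass is protected by default
  expect_true(all(cand$protected[cand$reaction_id == "BIOMASS"]))
  # explicit protection flags the synthase
  cand2 <- split_reversibles(md, protect = atp_synthase_patterns())
  expect_true(all(cand2$protected[cand2$reaction_id == "ATPS4r"]))
  expect_warning(split_reversibles(md, protect = "NO_SUCH_RXN"),
                 "matched no reaction")
})

test_that("the fig6d correction removes either adenylyltransferase, never both", {
  md <- prep_fixture("fig6d")$model
  p <- build_bilevel(md, split_reversibles(md))
  sol <- solve_correction(p)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 1)
  expect_true(sol$removals$reaction_id %in% c("R1", "R2"))
  expect_true(sol$certified_egc_free)
  expect_true(sol$growth_ok)
  alts <- enumerate_alternatives(p, k = 5)
  expect_length(alts, 2L)
  expect_setequal(vapply(alts, function(a) a$removals$reaction_id,
                         character(1)), c("R1", "R2"))
})

test_that("the fig6a correction breaks the transporter triangle", {
  md <- prep_fixture("fig6a")$model
  cand <- suppressWarnings(
    split_reversibles(md, protect = atp_synthase_patterns()))
  sol <- solve_correction(build_bilevel(md, cand))
  expect_equal(sol$objective, 1)
  expect_true(sol$removals$reaction_id %in% c("MALt2", "MALNAt", "NAt3"))
  expect_false("ATPS4r" %in% sol$removals$reaction_id)
  expect_true(sol$certified_egc_free && sol$growth_ok)
  # without protection the same triangle cut is still uniquely minimal:
  # removing the synthase would leave the proton-gradient cycle intact
  alts <- enumerate_alternatives(build_bilevel(md, split_reversibles(md)), 10)
  expect_setequal(unique(vapply(alts, function(a) a$removals$reaction_id,
                                character(1))),
                  c("MALt2", "MALNAt", "NAt3"))
})

test_that("forcing all binaries to zero is infeasible exactly when cycles exist", {
  md <- prep_fixture("fig6d")$model
  p <- build_bilevel(md, split_reversibles(md))
  expect_false(bilevel_feasible(p, rep(0, length(p$id_delta))))
  md0 <- prep_fixture("viable_control")$model
  p0 <- build_bilevel(md0, split_reversibles(md0))
  expect_true(bilevel_feasible(p0, rep(0, length(p0$id_delta))))
  sol0 <- solve_correction(p0)
  expect_equal(sol0$objective, 0)
  expect_equal(nrow(sol0$removals), 0L)
  expect_equal(biomass_impact(md0, sol0), 1, tolerance = 1e-9)
})

test_that("correction optimality matches exhaustive subset search", {
  for (nm in c("fig2", "fig6b", "fig6c", "two_pathway_biomass",
               "disjoint_double_fig6d")) {
    md <- prep_fixture(nm)$model
    cand <- split_reversibles(md)
    p <- build_bilevel(md, cand)
    sol <- solve_correction(p)
    oracle <- oracle_min_cuts(md, cand, p$T_g)
    expect_equal(sol$objective, oracle$size, info = nm)
    expect_true(paste(sol$removals$reaction_id, sol$removals$direction,
                      collapse = ";") %in%
                  vapply(oracle$cuts, paste, character(1), collapse = ";"),
                info = nm)
  }
})

test_that("the two-pass protocol retains the synthase on demand", {
  md <- prep_fixture("synthase_trap")$model
  tp <- run_two_pass(md)
  expect_equal(tp$simple$removals$reaction_id, "ATPS4r")
  expect_setequal(tp$synthase$removals$reaction_id, c("NAP1", "NAP2"))
  expect_equal(tp$synthase$objective, 2)
  expect_true(tp$synthase$certified_egc_free)
  # model without any synthase: second pass falls back with a warning
  md2 <- prep_fixture("fig6d")$model
  expect_warning(tp2 <- run_two_pass(md2), "no ATP synthase")
  expect_identical(tp2$simple$removals, tp2$synthase$removals)
})

test_that("biomass impact reflects the energy subsidy and never exceeds one", {
  md <- prep_fixture("two_pathway_biomass")$model
  sol <- solve_correction(build_bilevel(md, split_reversibles(md)))
  expect_equal(sol$removals$reaction_id, "PHANTOM")
  # hand-derived rich-medium optima: 2000/3 with the spurious ATP, 500 without
  expect_equal(sol$biomass_before, 2000 / 3, tolerance = 1e-6)
  expect_equal(sol$biomass_after, 500, tolerance = 1e-6)
  expect_equal(biomass_impact(md, sol), 0.75, tolerance = 1e-6)
  for (nm in cycle_fixture_names) {
    s <- solve_correction(build_bilevel(prep_fixture(nm)$model,
                                        split_reversibles(prep_fixture(nm)$model)))
    expect_lte(s$biomass_after, s$biomass_before + 1e-9)
  }
})

test_that("a growth threshold above the attainable optimum is a config error", {
  md <- prep_fixture("fig6d")$model
  expect_error(build_bilevel(md, split_reversibles(md),
                             correction_settings(tg = 2000,
                                                 tg_mode = "absolute")),
               "configuration error")
})

test_that("protected candidates never appear and weights steer the choice", {
  md <- prep_fixture("fig6d")$model
  # heavier R1 pushes the solution onto R2 at unchanged total cost structure
  w <- tibble::tibble(reaction_id = "R1", weight = 3)
  sol <- solve_correction(build_bilevel(md, split_reversibles(md, weights = w)))
  expect_equal(sol$removals$reaction_id, "R2")
  expect_equal(sol$objective, 1)
  # protecting both cycle members leaves no removal-only fix
  candp <- split_reversibles(md, protect = c("^R1$", "^R2$"))
  solp <- solve_correction(build_bilevel(md, candp))
  expect_equal(solp$status, "no_removal_correction")
  # weight monotonicity: doubling any weight never lowers the optimum
  base <- solve_correction(build_bilevel(md, split_reversibles(md)))$objective
  for (rid in c("R1", "R2", "GLCt")) {
    w2 <- tibble::tibble(reaction_id = rid, weight = 2)
    obj2 <- solve_correction(build_bilevel(
      md, split_reversibles(md, weights = w2)))$objective
    expect_gte(obj2, base - 1e-9)
  }
})

test_that("deterministic mode reproduces identical solutions", {
  md <- prep_fixture("fig6b")$model
  s1 <- solve_correction(build_bilevel(md, split_reversibles(md)))
  s2 <- solve_correction(build_bilevel(md, split_reversibles(md)))
  expect_identical(s1$removals, s2$removals)
})
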