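# Worked cycle optima below are hand-derived from the fixture stoichiometries
# (steady-state balances solved by hand under unit clamps) and re-checked by
# the enumeration oracle; see the fixtures documentation.

test_that("detection reproduces the hand-derived optima of the worked cycles", {
  cases <- list(
    list("fig6d", "GTP", 1.0),       # one full turn charges one GTP
    list("fig6a", "ATP", 0.25),      # 1 surplus proton/turn, 4 protons/ATP
    list("fig6a", "Hgradient", 1.0),
    list("fig2", "Hgradient", 1.0),
    list("fig6b", "Hgradient", 1.0),
    list("fig6c", "Hgradient", 3.0), # the pump translocates 3 protons/turn
    list("disjoint_double_fig6d", "GTP", 2.0),
    list("synthase_trap", "ATP", 0.5),
    list("two_pathway_biomass", "ATP", 1.0))
  for (cs in cases) {
    md <- prep_fixture(cs[[1]])$model
    rep <- suppressWarnings(detect_egc(md))
    expect_equal(rep$optimum[rep$label == cs[[2]]], cs[[3]],
                 tolerance = 1e-6,
                 info = paste(cs[[1]], cs[[2]]))
    expect_true(rep$has_egc[rep$label == cs[[2]]])
  }
})

test_that("a cycle-free control yields zero everywhere", {
  md <- prep_fixture("viable_control")$model
  rep <- detect_egc(md)
  expect_false(any(rep$has_egc))
  expect_true(all(rep$optimum[!is.na(rep$optimum)] <= 1e-9))
  expect_equal(attr(rep, "aggregate_optimum"), 0, tolerance = 1e-9)
  expect_true(all(rep$status[is.na(rep$optimum)] == "not integrated"))
})

test_that("every optimum is nonnegative and the aggregate dominates", {
  for (nm in all_fixture_names) {
    rep <- suppressWarnings(detect_egc(prep_fixture(nm)$model))
    expect_true(all(rep$optimum[!is.na(rep$optimum)] >= 0))
    expect_gte(attr(rep, "aggregate_optimum") + 1e-9,
               max(c(0, rep$optimum), na.rm = TRUE))
  }
})

test_that("doubling the clamp doubles every optimum (LP homogeneity)", {
  for (nm in c("fig6a", "fig6c", "fig6d")) {
    md <- prep_fixture(nm)$model
    r1 <- suppressWarnings(detect_egc(md, detection_settings(clamp = 1)))
    r2 <- suppressWarnings(detect_egc(md, detection_settings(clamp = 2)))
    expect_equal(r2$optimum, 2 * r1$optimum, tolerance = 1e-8)
  }
})

test_that("adding a reaction never removes a detected cycle", {
  md <- prep_fixture("fig6d")$model
  r1 <- detect_egc(md)
  md$reactions <- dplyr::bind_rows(
    md$reactions,
    tibble::tibble(id = "EXTRA", name = "EXTRA",
                   stoichiometry = list(c(so4_c = -1, extra_c = 1)),
                   lower_bound = -1000, upper_bound = 1000,
                   is_exchange = FALSE, is_dissipation = FALSE,
                   gene_rule = NA_character_))
  md$metabolites <- dplyr::bind_rows(
    md$metabolites,
    tibble::tibble(id = "extra_c", name = "extra_c", compartment = "c",
                   formula = NA_character_, charge = NA_real_,
                   boundary = FALSE))
  r2 <- detect_egc(md)
  expect_true(all(r2$has_egc[r1$has_egc]))
  expect_gte(r2$optimum[r2$label == "GTP"], r1$optimum[r1$label == "GTP"])
})

test_that("the cycle-count bound requires unit clamps and adds up", {
  md <- prep_fixture("disjoint_double_fig6d")$model
  rep <- detect_egc(md)
  expect_equal(count_lower_bound(rep, "GTP"), 2.0, tolerance = 1e-6)
  rep2 <- detect_egc(md, detection_settings(clamp = 2))
  expect_error(count_lower_bound(rep2, "GTP"), "unit clamp")
  expect_equal(count_lower_bound(rep, "ATP"), 0)  # not integrated -> zero
})

test_that("cycle support extraction returns the planted members only", {
  md <- prep_fixture("fig6d")$model
  expect_setequal(enumerate_cycle_support(md, "GTP"),
                  c("R1", "R2", "EDR_GTP"))
  md2 <- prep_fixture("fig6a")$model
  sup <- enumerate_cycle_support(md2, "ATP")
  expect_setequal(sup, c("MALt2", "MALNAt", "NAt3", "ATPS4r", "EDR_ATP"))
  # exchanges are blocked: none can appear in any support
  expect_false(any(md2$reactions$is_exchange[match(sup, md2$reactions$id)]))
  # no cycle -> error
  md3 <- prep_fixture("viable_control")$model
  expect_error(enumerate_cycle_support(md3, "ATP"), "no energy-generating")
})

test_that("detection verdicts equal exhaustive cycle enumeration on fixtures", {
  for (nm in all_fixture_names) {
    md <- prep_fixture(nm)$model
    rep <- suppressWarnings(detect_egc(md))
    for (k in seq_len(nrow(rep))) {
      expect_identical(rep$has_egc[k], oracle_has_egc(md, rep$label[k]),
                       info = paste(nm, rep$label[k]))
    }
  }
})

test_that("detection requires attached dissipation reactions", {
  m <- normalize_model(make_fixture("fig6d")$model)
  expect_error(detect_egc(m), "attach_dissipation")
})
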