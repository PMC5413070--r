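test_that("the default catalog carries all fifteen energy currencies", {
  cat_tbl <- dissipation_catalog()
  expect_equal(nrow(cat_tbl), 15L)
  expect_setequal(cat_tbl$label,
                  c("ATP", "CTP", "GTP", "UTP", "ITP", "NADH", "NADPH",
                    "FADH2", "FMNH2", "Q8H2", "MQL8", "DMMQL8", "AcCoA",
                    "GluL", "Hgradient"))
  # every template is a pure discharge: at least one substrate, one product
  for (eq in cat_tbl$equation) {
    st <- parse_equation(eq)$stoichiometry
    expect_true(any(st < 0) && any(st > 0))
  }
})

test_that("templates resolve against BiGG-style models with correct integration", {
  md <- prep_fixture("viable_control")$model
  drs <- attr(md, "dissipation")
  atp <- drs[drs$label == "ATP", ]
  expect_equal(atp$integration, 1)
  expect_true(atp$active)
  expect_equal(sort(names(atp$stoichiometry[[1]])),
               sort(c("atp_c", "h2o_c", "adp_c", "pi_c", "h_c")))
  expect_equal(atp$stoichiometry[[1]][["atp_c"]], -1)
  # integration is exactly k/n for template size n
  expect_true(all(abs(drs$integration - drs$n_resolved / drs$n_species)
                  < 1e-12))
  # no NADH-family metabolite: partially integrated and inactive
  nadh <- drs[drs$label == "NADH", ]
  expect_lt(nadh$integration, 1)
  expect_false(nadh$active)
})

test_that("the proton gradient needs a second compartment", {
  # cytosol-only model: no periplasmic/external proton, template unresolved
  rx <- reactions_from_equations(tibble::tibble(
    id = c("R1", "BIO"), equation = c("h_c + a_c -> b_c", "b_c ->")))
  m <- build_fixture_model_for_test(rx)
  drs <- build_dissipation_reactions(m)
  hg <- drs[drs$label == "Hgradient", ]
  expect_false(hg$active)
  expect_true("h[p]" %in% hg$unresolved[[1]])
  # periplasm present: resolves to h_p -> h_c
  md <- prep_fixture("fig6b")$model
  hg2 <- attr(md, "dissipation")
  hg2 <- hg2[hg2$label == "Hgradient", ]
  expect_equal(hg2$stoichiometry[[1]][c("h_p", "h_c")],
               c(h_p = -1, h_c = 1))
})

test_that("ModelSEED-style identifiers resolve through the synonym table", {
  rx <- reactions_from_equations(tibble::tibble(
    id = c("rxn1", "BIO"),
    equation = c("cpd00002_c0 + cpd00001_c0 -> cpd00008_c0 + cpd00009_c0 + cpd00067_c0",
                 "cpd00002_c0 ->")))
  met_ids <- sort(unique(unlist(lapply(rx$stoichiometry, names))))
  m <- metabolic_model(
    tibble::tibble(id = met_ids, compartment = "c0"),
    rx, "BIO", "modelseed")
  drs <- build_dissipation_reactions(m)
  atp <- drs[drs$label == "ATP", ]
  expect_true(atp$active)
  expect_equal(atp$stoichiometry[[1]][["cpd00002_c0"]], -1)
  expect_equal(atp$stoichiometry[[1]][["cpd00067_c0"]], 1)
})

test_that("attachment is invertible, idempotent-guarded and collision-safe", {
  m <- normalize_model(make_fixture("fig6d")$model)
  md <- attach_dissipation(m)
  expect_true(any(md$reactions$is_dissipation))
  expect_true(all(md$reactions$lower_bound[md$reactions$is_dissipation] == 0))
  back <- detach_dissipation(md)
  expect_identical(m$reactions, back$reactions)
  expect_identical(m$metabolites, back$metabolites)
  expect_warning(again <- attach_dissipation(md), "already attached")
  expect_identical(again$reactions, md$reactions)
  # an existing reaction named like the dissipation id is not clobbered
  rx <- reactions_from_equations(tibble::tibble(
    id = c("EDR_GTP", "R2", "BIO"),
    equation = c("gtp_c + h2o_c -> gdp_c + pi_c + h_c",
                 "gdp_c + pi_c + h_c -> gtp_c + h2o_c",
                 "gtp_c ->")))
  m2 <- build_fixture_model_for_test(rx)
  md2 <- attach_dissipation(m2)
  expect_equal(sum(grepl("^EDR_GTP", md2$reactions$id)), 2L)
  expect_false(is.null(attr(md2, "dissipation_aliases")))
})

test_that("a cycle-free model stays cycle-free after attachment", {
  # dissipation reactions strictly consume their currency, so they cannot
  # close a cycle on their own
  for (s in 1:5) {
    rmod <- make_random_egc_model(n_reactions = 11, n_planted = 0, seed = s)
    md <- attach_dissipation(normalize_model(rmod$model))
    rep <- suppressWarnings(detect_egc(md))
    expect_false(any(rep$has_egc))
    for (l in rep$label[rep$status != "not integrated"])
      expect_false(oracle_has_egc(md, l))
  }
})
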