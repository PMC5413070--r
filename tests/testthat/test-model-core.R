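test_that("equation parsing handles coefficients, reversibility and merging", {
  p <- parse_equation("atp_c + h2o_c -> adp_c + pi_c + h_c")
  expect_false(p$reversible)
  expect_equal(p$stoichiometry[["atp_c"]], -1)
  expect_equal(p$stoichiometry[["h_c"]], 1)
  p <- parse_equation("2 h_e <=> 2 h_c")
  expect_true(p$reversible)
  expect_equal(p$stoichiometry, c(h_c = 2, h_e = -2))
  # species appearing on both sides cancel
  p <- parse_equation("a_c + b_c -> a_c + c_c")
  expect_equal(sort(names(p$stoichiometry)), c("b_c", "c_c"))
})

test_that("models round-trip through SBML and JSON without loss", {
  for (nm in c("fig6d", "fig6a", "viable_control")) {
    m <- make_fixture(nm)$model
    canon <- function(x) lapply(x$reactions$stoichiometry,
                                function(s) s[order(names(s))])
    f1 <- withr::local_tempfile(fileext = ".xml")
    write_model_sbml(m, f1)
    m2 <- read_model_sbml(f1)
    expect_identical(canon(m), canon(m2))
    expect_identical(m$reactions$id, m2$reactions$id)
    expect_equal(m$reactions$lower_bound, m2$reactions$lower_bound)
    expect_equal(m$reactions$upper_bound, m2$reactions$upper_bound)
    expect_identical(m$biomass_reaction_id, m2$biomass_reaction_id)
    expect_identical(sort(m$metabolites$id), sort(m2$metabolites$id))

    f2 <- withr::local_tempfile(fileext = ".json")
    write_model_json(m, f2)
    m3 <- read_model_json(f2)
    expect_identical(canon(m), canon(m3))
    expect_equal(m$reactions$lower_bound, m3$reactions$lower_bound)
  }
})

test_that("SBML fbc bounds and annotations pass through verbatim", {
  m <- make_fixture("fig6a")$model
  i <- match("MALt2", m$reactions$id)
  expect_equal(m$reactions$lower_bound[i], -1000)
  f <- withr::local_tempfile(fileext = ".xml")
  write_model_sbml(m, f)
  doc <- xml2::read_xml(f)
  xml2::xml_ns_strip(doc)
  par <- xml2::xml_find_first(doc, ".//parameter[@id='R_MALt2_lb']")
  expect_equal(as.numeric(xml2::xml_attr(par, "value")), -1000)
  m2 <- read_model_sbml(f)
  expect_equal(m2$reactions$lower_bound[match("MALt2", m2$reactions$id)],
               -1000)
  expect_equal(m2$reactions$upper_bound[match("MALt2", m2$reactions$id)],
               1000)
})

test_that("referential integrity is enforced with the dangling id named", {
  expect_error(
    metabolic_model(
      metabolites = tibble::tibble(id = "a_c", compartment = "c"),
      reactions = tibble::tibble(id = c("R1", "BIO"),
                                 stoichiometry = list(c(a_c = -1, ghost_c = 1),
                                                      c(a_c = -1)),
                                 lower_bound = 0, upper_bound = 1),
      biomass_reaction_id = "BIO", namespace = "bigg"),
    "ghost_c")
})

test_that("a missing biomass candidate raises an error naming the heuristic", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    id = "nobio", namespace = "bigg",
    metabolites = list(list(id = "a_c", compartment = "c")),
    reactions = list(list(id = "R1", metabolites = list(a_c = -1),
                          lower_bound = 0, upper_bound = 1))),
    f, auto_unbox = TRUE)
  expect_error(read_model_json(f), "biomass|growth")
})

test_that("normalization zeroes the ATPM lower bound and logs it", {
  rx <- reactions_from_equations(tibble::tibble(
    id = c("ATPM", "EX_a", "At", "BIO"),
    equation = c("atp_c + h2o_c -> adp_c + pi_c + h_c",
                 "a_e ->", "a_e -> a_c", "a_c ->")))
  rx$lower_bound[1] <- 8.39
  rx$lower_bound[2] <- -1000
  m <- build_fixture_model_for_test(rx)
  mn <- normalize_model(m)
  i <- match("ATPM", mn$reactions$id)
  expect_equal(mn$reactions$lower_bound[i], 0)
  lg <- normalization_log(mn)
  expect_true(any(lg$change == "atpm_lower_bound" & lg$reaction_id == "ATPM"))
  # a model without an ATPM match logs a marker, not an error
  m2 <- make_fixture("fig2")$model
  expect_silent(mn2 <- normalize_model(m2))
  expect_true(any(normalization_log(mn2)$change == "atpm_not_found"))
})

test_that("uptake-written exchanges are flipped without changing the polytope", {
  rx <- tibble::tibble(
    id = c("EX_glc", "GLCt", "BIO"),
    equation = c("-> glc_e", "glc_e -> glc_c", "glc_c ->"),
    lower_bound = c(0, 0, 0), upper_bound = c(10, 1000, 1000))
  m <- build_fixture_model_for_test(reactions_from_equations(rx))
  before <- fba_optimum(m)$objective      # uptake as written: max 10
  mn <- normalize_model(m)
  i <- match("EX_glc", mn$reactions$id)
  expect_equal(mn$reactions$stoichiometry[[i]], c(glc_e = -1))
  expect_equal(mn$reactions$lower_bound[i], -10)
  expect_equal(mn$reactions$upper_bound[i], 0)
  expect_true(any(normalization_log(mn)$change == "exchange_flip"))
  # sign relabelling leaves the achievable biomass unchanged
  expect_equal(fba_optimum(mn)$objective, before)
})

test_that("normalization is idempotent", {
  m <- normalize_model(make_fixture("fig6a")$model)
  m2 <- normalize_model(m)
  expect_identical(m$reactions, m2$reactions)
  expect_false(any(normalization_log(m2)$change == "exchange_flip"))
})

test_that("viability is monotone in the threshold and zero when disconnected", {
  m <- normalize_model(make_fixture("viable_control")$model)
  v <- check_viability(m, threshold = 1e-6)
  expect_true(v$viable)
  expect_equal(v$optimum, 500)            # hand-derived rich-medium optimum
  for (thr in c(0, 1, 100, 499)) expect_true(check_viability(m, thr)$viable)
  expect_false(check_viability(m, 500 + 1e-3)$viable)
  # biomass consuming a metabolite nothing produces
  rx <- reactions_from_equations(tibble::tibble(
    id = c("EX_a", "At", "BIO"),
    equation = c("a_e ->", "a_e -> a_c", "a_c + orphan_c ->")))
  rx$lower_bound[1] <- -1000
  m0 <- build_fixture_model_for_test(rx)
  v0 <- check_viability(normalize_model(m0), 1e-6)
  expect_false(v0$viable)
  expect_equal(v0$optimum, 0)
})

test_that("elemental and charge balance screening matches hand bookkeeping", {
  mets <- tibble::tibble(
    id = c("atp_c", "h2o_c", "adp_c", "pi_c", "h_c"),
    compartment = "c",
    formula = c("C10H12N5O13P3", "H2O", "C10H12N5O10P2", "HO4P", "H"),
    charge = c(-4, 0, -3, -2, 1))
  rxns <- reactions_from_equations(tibble::tibble(
    id = c("HYD", "BROKEN", "BIO"),
    equation = c("atp_c + h2o_c -> adp_c + pi_c + h_c",
                 "atp_c -> adp_c", "atp_c ->")))
  m <- metabolic_model(mets, rxns, "BIO", "bigg")
  bal <- check_balance(m)
  expect_true(bal$balanced[bal$reaction_id == "HYD"])
  expect_equal(bal$charge_delta[bal$reaction_id == "HYD"], 0)
  broken <- bal[bal$reaction_id == "BROKEN", ]
  expect_false(broken$balanced)
  d <- broken$element_deltas[[1]]
  expect_equal(d[["O"]], -3)
  expect_equal(d[["P"]], -1)
  expect_false("H" %in% names(d))          # hydrogen balances in ADP + nothing
  # models without formulas are skipped, not judged
  m2 <- make_fixture("fig6d")$model
  bal2 <- check_balance(m2)
  internal <- bal2$status != "exempt"
  expect_true(all(bal2$status[internal] == "skipped: no formula"))
})
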