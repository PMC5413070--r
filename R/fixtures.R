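## assemble a fixture model from an equation table; compartments are taken
## from the id suffix after the final underscore (BiGG style)
build_fixture_model <- function(id, rxn_tbl, biomass = "BIOMASS",
                                namespace = "bigg") {
  rxns <- reactions_from_equations(rxn_tbl)
  met_ids <- sort(unique(unlist(lapply(rxns$stoichiometry, names))))
  mets <- tibble::tibble(id = met_ids,
                         compartment = sub(".*_", "", met_ids))
  metabolic_model(mets, rxns, biomass, namespace, id = id)
}

## shared nutrient pathway so every fixture is viable: exchange written in
## the secretion convention (negative flux = uptake)
viability_rxns <- function(biomass_eq = "glc_c ->") {
  tibble::tribble(
    ~id,       ~equation,          ~lower_bound, ~upper_bound,
    "EX_glc",  "glc_e ->",         -1000,        1000,
    "GLCt",    "glc_e -> glc_c",   0,            1000,
    "BIOMASS", biomass_eq,         0,            1000)
}

planted <- function(target, members, min_cut_size) {
  tibble::tibble(target = target, members = list(members),
                 min_cut_size = min_cut_size)
}

FIXTURE_NAMES <- c("fig2", "fig6a", "fig6b", "fig6c", "fig6d",
                   "viable_control", "two_pathway_biomass",
                   "disjoint_double_fig6d", "synthase_trap")

#' Toy models reproducing published energy-generating cycle motifs
#'
#' Small, fully specified models (at most ~20 reactions) that reproduce the
#' classic cycle motifs observed in published reconstructions, each with a
#' nutrient pathway and biomass reaction so viability is testable, plus
#' cycle-free controls:
#'
#' * `fig2` — a metabolite/proton symporter paired with a proton-less
#'   uniporter for the same metabolite; together they pump protons and build
#'   a gradient from nothing.
#' * `fig6a` — a malate/2H+ symporter, malate/Na+ symporter and Na+/H+
#'   antiporter triangle that leaves one surplus periplasmic proton per turn,
#'   driving an ATP synthase (4 protons per ATP, hence an ATP optimum of
#'   0.25 under unit clamps).
#' * `fig6b` — tartrate facilitated transport plus a
#'   tartrate/succinate antiporter, succinate/aspartate antiporter and
#'   aspartate/proton symporter, which together export one proton per turn.
#' * `fig6c` — a proton-pumping NADH:menaquinone oxidoreductase closed by a
#'   four-enzyme chain (malate dehydrogenase, a reversed malate oxidase, a
#'   superoxide dismutase and a quinol:superoxide oxidoreductase); a
#'   qualitative reconstruction, not the strain-exact stoichiometry.
#' * `fig6d` — two sulfate adenylyltransferases with mismatched energy
#'   stoichiometry (the reverse reaction charges an extra GTP); the proton
#'   consumed by the forward enzyme keeps cytosolic protons balanced.
#' * `viable_control` — respiration plus biomass, no cycle; every detection
#'   optimum is zero.
#' * `two_pathway_biomass` — biomass fed both by respiration and by an
#'   erroneous free phosphorylation; correcting the cycle drops the rich-
#'   medium biomass optimum from 2000/3 to 500 (a 25% reduction).
#' * `disjoint_double_fig6d` — two reaction-disjoint copies of the `fig6d`
#'   cycle sharing the nucleotide pool, so the GTP optimum is 2 and the
#'   minimal cut has size 2.
#' * `synthase_trap` — a sodium-motive ATP synthase fed by two erroneous
#'   sodium pumps; the cheapest unprotected correction removes the synthase,
#'   the synthase-protected pass must remove both pumps.
#'
#' Every fixture's ground truth (`planted_egcs`, minimal cut sizes, biomass
#' optima) is re-derived in the package's test suite by enumeration, never
#' asserted from memory.
#'
#' @param name one of
#'   `r paste0('"', c("fig2","fig6a","fig6b","fig6c","fig6d","viable_control","two_pathway_biomass","disjoint_double_fig6d","synthase_trap"), '"', collapse = ", ")`.
#' @return A list with elements `model` (a [metabolic_model()]) and `spec`
#'   (name, description, `planted_egcs` tibble with `target`, `members`,
#'   `min_cut_size`, logical `viable`, and the hand-computed rich-medium
#'   `biomass_optimum`).
#' @examples
#' fx <- make_fixture("fig6d")
#' fx$model
#' fx$spec$planted_egcs
#' @export
make_fixture <- function(name) {
  if (!name %in% FIXTURE_NAMES)
    stop("unknown fixture '", name, "'; available: ",
         paste(FIXTURE_NAMES, collapse = ", "))
  switch(
    name,
    fig2 = {
      rx <- dplyr::bind_rows(tibble::tribble(
        ~id,    ~equation,
        "MSYM", "m_c + h_c <-> m_e + h_e",
        "MUNI", "m_e <-> m_c"), viability_rxns())
      list(model = build_fixture_model("fig2", rx),
           spec = list(
             name = "fig2",
             description = paste("proton-translocating symporter paired with",
                                 "a proton-less uniporter"),
             planted_egcs = planted("Hgradient",
                                    c("MSYM", "MUNI", "EDR_Hgradient"), 1L),
             viable = TRUE, biomass_optimum = 1000))
    },
    fig6a = {
      rx <- dplyr::bind_rows(tibble::tribble(
        ~id,      ~equation,
        "MALt2",  "mal_c + 2 h_c <-> mal_e + 2 h_e",
        "MALNAt", "mal_e + na1_e <-> mal_c + na1_c",
        "NAt3",   "na1_c + h_e <-> na1_e + h_c",
        "ATPS4r", "adp_c + pi_c + 4 h_e <-> atp_c + h2o_c + 3 h_c"),
        viability_rxns())
      list(model = build_fixture_model("fig6a", rx),
           spec = list(
             name = "fig6a",
             description = paste("malate/Na+/proton transporter triangle",
                                 "driving an ATP synthase"),
             planted_egcs = dplyr::bind_rows(
               planted("ATP", c("MALt2", "MALNAt", "NAt3", "ATPS4r",
                                "EDR_ATP"), 1L),
               planted("Hgradient", c("MALt2", "MALNAt", "NAt3",
                                      "EDR_Hgradient"), 1L)),
             viable = TRUE, biomass_optimum = 1000))
    },
    fig6b = {
      rx <- dplyr::bind_rows(tibble::tribble(
        ~id,          ~equation,
        "TARTRtpp",   "tartr_p <-> tartr_c",
        "TARTRt7pp",  "tartr_c + succ_p <-> tartr_p + succ_c",
        "SUCASPtpp",  "succ_c + asp_p <-> succ_p + asp_c",
        "ASPt2pp",    "asp_p + h_p <-> asp_c + h_c"),
        viability_rxns())
      list(model = build_fixture_model("fig6b", rx),
           spec = list(
             name = "fig6b",
             description = paste("tartrate facilitated transport driving an",
                                 "antiporter/symporter proton pump"),
             planted_egcs = planted("Hgradient",
                                    c("TARTRtpp", "TARTRt7pp", "SUCASPtpp",
                                      "ASPt2pp", "EDR_Hgradient"), 1L),
             viable = TRUE, biomass_optimum = 1000))
    },
    fig6c = {
      rx <- dplyr::bind_rows(tibble::tribble(
        ~id,        ~equation,
        "NADH17pp", "nadh_c + mqn8_c + 4 h_c -> nad_c + mql8_c + 3 h_p",
        "MDH",      "mal_c + nad_c <-> oaa_c + nadh_c + h_c",
        "MOX",      "mal_c + o2_c <-> oaa_c + h2o2_c",
        "SPODM",    "2 o2s_c + 2 h_c -> o2_c + h2o2_c",
        "QOR",      "mql8_c + 2 o2_c -> mqn8_c + 2 o2s_c + 2 h_c"),
        viability_rxns())
      list(model = build_fixture_model("fig6c", rx),
           spec = list(
             name = "fig6c",
             description = paste("proton-pumping NADH:menaquinone",
                                 "oxidoreductase closed by a four-enzyme",
                                 "chain including superoxide dismutase"),
             planted_egcs = planted("Hgradient",
                                    c("NADH17pp", "MDH", "MOX", "SPODM",
                                      "QOR", "EDR_Hgradient"), 1L),
             viable = TRUE, biomass_optimum = 1000))
    },
    fig6d = {
      rx <- dplyr::bind_rows(tibble::tribble(
        ~id,  ~equation,
        "R1", "atp_c + so4_c + h_c -> aps_c + ppi_c",
        "R2", "aps_c + ppi_c + gdp_c + pi_c -> atp_c + gtp_c + so4_c + h2o_c"),
        viability_rxns())
      list(model = build_fixture_model("fig6d", rx),
           spec = list(
             name = "fig6d",
             description = paste("paired sulfate adenylyltransferases with",
                                 "mismatched energy stoichiometry (extra GTP",
                                 "charged on the return reaction)"),
             planted_egcs = planted("GTP", c("R1", "R2", "EDR_GTP"), 1L),
             viable = TRUE, biomass_optimum = 1000))
    },
    viable_control = {
      rx <- tibble::tribble(
        ~id,       ~equation,                                      ~lower_bound, ~upper_bound,
        "EX_glc",  "glc_e ->",                                     -1000, 1000,
        "EX_h2o",  "h2o_e ->",                                     -1000, 1000,
        "EX_co2",  "co2_e ->",                                     -1000, 1000,
        "GLCt",    "glc_e -> glc_c",                               0, 1000,
        "H2Ot",    "h2o_e <-> h2o_c",                              -1000, 1000,
        "CO2t",    "co2_c -> co2_e",                               0, 1000,
        "RESP",    "glc_c + 2 adp_c + 2 pi_c -> 2 atp_c + 2 h_c + co2_c", 0, 1000,
        "BIOMASS", "glc_c + 2 atp_c + 2 h_c -> 2 adp_c + 2 pi_c + h2o_c", 0, 1000)
      list(model = build_fixture_model("viable_control", rx),
           spec = list(
             name = "viable_control",
             description = "respiration plus biomass, no planted cycle",
             planted_egcs = planted(character(0), list(), integer(0))[0, ],
             viable = TRUE, biomass_optimum = 500))
    },
    two_pathway_biomass = {
      rx <- tibble::tribble(
        ~id,       ~equation,                                      ~lower_bound, ~upper_bound,
        "EX_glc",  "glc_e ->",                                     -1000, 1000,
        "EX_h2o",  "h2o_e ->",                                     -1000, 1000,
        "EX_co2",  "co2_e ->",                                     -1000, 1000,
        "EX_hco3", "hco3_e ->",                                    -1000, 1000,
        "GLCt",    "glc_e -> glc_c",                               0, 1000,
        "H2Ot",    "h2o_e <-> h2o_c",                              -1000, 1000,
        "CO2t",    "co2_c -> co2_e",                               0, 1000,
        "HCO3t",   "hco3_c -> hco3_e",                             0, 1000,
        "RESP",    "glc_c + 2 adp_c + 2 pi_c -> 2 atp_c + 2 h_c + 2 co2_c", 0, 1000,
        "CARB",    "co2_c + h_c -> hco3_c",                        0, 1000,
        "PHANTOM", "adp_c + pi_c + h_c -> atp_c + h2o_c",          0, 1000,
        "BIOMASS", "glc_c + 2 atp_c -> 2 adp_c + 2 pi_c",          0, 1000)
      list(model = build_fixture_model("two_pathway_biomass", rx),
           spec = list(
             name = "two_pathway_biomass",
             description = paste("biomass fed by respiration and by an",
                                 "erroneous free phosphorylation"),
             planted_egcs = planted("ATP", c("PHANTOM", "EDR_ATP"), 1L),
             viable = TRUE, biomass_optimum = 2000 / 3,
             biomass_optimum_corrected = 500))
    },
    disjoint_double_fig6d = {
      rx <- dplyr::bind_rows(tibble::tribble(
        ~id,   ~equation,
        "R1A", "atp_c + so4_c + h_c -> aps_c + ppi_c",
        "R2A", "aps_c + ppi_c + gdp_c + pi_c -> atp_c + gtp_c + so4_c + h2o_c",
        "R1B", "atp_c + so4b_c + h_c -> apsb_c + ppib_c",
        "R2B", "apsb_c + ppib_c + gdp_c + pi_c -> atp_c + gtp_c + so4b_c + h2o_c"),
        viability_rxns())
      list(model = build_fixture_model("disjoint_double_fig6d", rx),
           spec = list(
             name = "disjoint_double_fig6d",
             description = paste("two reaction-disjoint copies of the fig6d",
                                 "cycle sharing the nucleotide pool"),
             planted_egcs = dplyr::bind_rows(
               planted("GTP", c("R1A", "R2A", "EDR_GTP"), 2L),
               planted("GTP", c("R1B", "R2B", "EDR_GTP"), 2L)),
             viable = TRUE, biomass_optimum = 1000))
    },
    synthase_trap = {
      rx <- dplyr::bind_rows(tibble::tribble(
        ~id,      ~equation,
        "NAP1",   "na1_c -> na1_e",
        "NAP2",   "na1_c -> na1_e",
        "ATPS4r", "4 na1_e + adp_c + pi_c + h_c -> atp_c + 4 na1_c + h2o_c"),
        viability_rxns())
      list(model = build_fixture_model("synthase_trap", rx),
           spec = list(
             name = "synthase_trap",
             description = paste("sodium-motive ATP synthase fed by two",
                                 "erroneous sodium pumps; the cheapest",
                                 "unprotected fix removes the synthase"),
             planted_egcs = dplyr::bind_rows(
               planted("ATP", c("NAP1", "ATPS4r", "EDR_ATP"), 1L),
               planted("ATP", c("NAP2", "ATPS4r", "EDR_ATP"), 1L)),
             viable = TRUE, biomass_optimum = 1000))
    })
}

#' Seeded random models with planted energy-generating cycles
#'
#' Composes a viable linear pathway (nutrient uptake, a conversion chain,
#' biomass) with `n_planted` cycle motifs and tree-shaped filler conversions
#' that cannot close cycles.  Two motif families are available:
#'
#' * `atp` (cofactor mismatch): an erroneous free phosphorylation
#'   `adp + pi + h -> atp + h2o`, a cycle once the ATP dissipation reaction
#'   is attached; each planted motif contributes exactly 1 to the ATP
#'   detection optimum under unit clamps.
#' * `proton` (transporter mismatch): a metabolite/proton export symporter
#'   paired with a proton-less importer, contributing 1 to the
#'   proton-gradient optimum.
#'
#' The generator is fully deterministic under `seed` and restores the
#' caller's random-number state.
#'
#' @param n_reactions total number of reactions (chain and filler scale to
#'   reach it; at most 60).
#' @param n_planted number of cycle motifs.
#' @param seed integer seed.
#' @param motifs `"mixed"` (seeded choice per motif), `"atp"`, or
#'   `"proton"`.
#' @return A list with `model` and `spec` as in [make_fixture()]; the spec's
#'   `planted_egcs` lists each motif with its member reactions, and
#'   `expected_optima` gives the per-target detection optima implied by the
#'   construction.
#' @export
make_random_egc_model <- function(n_reactions = 30, n_planted = 1, seed = 1,
                                  motifs = c("mixed", "atp", "proton")) {
  stopifnot(n_reactions <= 60, n_reactions >= 10 + 2 * n_planted)
  motifs <- match.arg(motifs)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)

  rows <- tibble::tribble(
    ~id,      ~equation,           ~lower_bound, ~upper_bound,
    "EX_nut", "nut_e ->",          -1000,        1000,
    "NUTt",   "nut_e -> nut_c",    0,            1000,
    ## ATP pool so the ATP dissipation template always integrates
    "NGAM",   "atp_c + h2o_c -> adp_c + pi_c + h_c", 0, 1000)
  motif_rows <- list()
  egcs <- list()
  n_atp <- 0L; n_h <- 0L
  for (j in seq_len(n_planted)) {
    kind <- switch(motifs, atp = "atp", proton = "proton",
                   mixed = sample(c("atp", "proton"), 1))
    if (kind == "atp") {
      n_atp <- n_atp + 1L
      id <- sprintf("PHANTOM%d", j)
      motif_rows[[j]] <- tibble::tibble(
        id = id, equation = "adp_c + pi_c + h_c -> atp_c + h2o_c",
        lower_bound = 0, upper_bound = 1000)
      egcs[[j]] <- planted("ATP", c(id, "EDR_ATP"), 1L)
    } else {
      n_h <- n_h + 1L
      sym <- sprintf("SYM%d", j); uni <- sprintf("UNI%d", j)
      x <- sprintf("x%d", j)
      motif_rows[[j]] <- tibble::tibble(
        id = c(sym, uni),
        equation = c(sprintf("%s_c + h_c -> %s_e + h_e", x, x),
                     sprintf("%s_e -> %s_c", x, x)),
        lower_bound = 0, upper_bound = 1000)
      egcs[[j]] <- planted("Hgradient", c(sym, uni, "EDR_Hgradient"), 1L)
    }
  }
  rows <- dplyr::bind_rows(rows, motif_rows)

  ## conversion chain from the nutrient to the biomass precursor
  used <- nrow(rows) + 1L          # +1 for the biomass reaction added below
  n_chain <- max(2L, min(6L, n_reactions - used - 1L))
  chain_ids <- sprintf("C%d", seq_len(n_chain))
  chain_mets <- c("nut_c", sprintf("im%d_c", seq_len(n_chain)))
  rev_flag <- sample(c(TRUE, FALSE), n_chain, replace = TRUE)
  rows <- dplyr::bind_rows(rows, tibble::tibble(
    id = chain_ids,
    equation = sprintf("%s %s %s", chain_mets[-length(chain_mets)],
                       ifelse(rev_flag, "<->", "->"), chain_mets[-1]),
    lower_bound = ifelse(rev_flag, -1000, 0), upper_bound = 1000))
  rows <- dplyr::bind_rows(rows, tibble::tibble(
    id = "BIOMASS", equation = sprintf("%s ->", chain_mets[length(chain_mets)]),
    lower_bound = 0, upper_bound = 1000))

  ## tree-shaped filler: each new reaction converts an existing carbon
  ## metabolite into a fresh one, so no new cycle can arise
  n_fill <- n_reactions - nrow(rows)
  sources <- chain_mets
  for (k in seq_len(max(0L, n_fill))) {
    src <- sample(sources, 1)
    new <- sprintf("f%d_c", k)
    rev <- sample(c(TRUE, FALSE), 1)
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      id = sprintf("F%d", k),
      equation = sprintf("%s %s %s", src, ifelse(rev, "<->", "->"), new),
      lower_bound = ifelse(rev, -1000, 0), upper_bound = 1000))
    sources <- c(sources, new)
  }

  model <- build_fixture_model(sprintf("random_s%d_p%d", seed, n_planted),
                               rows)
  expected <- c(ATP = n_atp, Hgradient = n_h)
  list(model = model,
       spec = list(name = model$id,
                   description = "seeded random model with planted motifs",
                   planted_egcs = if (length(egcs)) dplyr::bind_rows(egcs)
                                  else planted(character(0), list(),
                                               integer(0))[0, ],
                   viable = TRUE, biomass_optimum = 1000,
                   expected_optima = expected))
}
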