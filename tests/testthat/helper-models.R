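# small ad-hoc models for unit tests; compartment taken from the id suffix
build_fixture_model_for_test <- function(rxns, biomass = "BIO",
                                         namespace = "bigg", id = "test") {
  met_ids <- sort(unique(unlist(lapply(rxns$stoichiometry, names))))
  mets <- tibble::tibble(id = met_ids, compartment = sub(".*_", "", met_ids))
  metabolic_model(mets, rxns, biomass, namespace, id = id)
}
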