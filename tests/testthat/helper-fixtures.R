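# Shared builders: one richly populated, valid observation per kind.

fx_concept <- function(system, code, display = NULL) {
  concept_ref(system, code, display)
}

make_obs <- function(kind, id = paste0(kind, "-1"), ...) {
  extra <- list(...)
  payload <- switch(kind,
    culture = list(
      result = detection_concept("detected"),
      organism = fx_concept("snomed", "112283007",
                            "Escherichia coli (organism)")),
    colony_count = list(
      code = fx_concept("loinc", "49223-1",
        "Colony count [#/volume] in Unspecified specimen by Visual count"),
      quantity = quantity(100000, "/mL")),
    susceptibility = list(
      agent = fx_concept("loinc", "18945-6", "Methicillin [Susceptibility]"),
      mic = quantity(2, "ug/mL"),
      interpretation = "R", scheme = "EUCAST", scheme_version = "13.0"),
    microscopy = list(
      result = detection_concept("detected"),
      method = fx_concept("snomed", "104157003",
                          "Light microscopy (procedure)"),
      organism = fx_concept("snomed", "112283007",
                            "Escherichia coli (organism)"),
      morphology = "Gram-negative rods",
      score = list(code = fx_concept("loinc", "75371-5",
        "Bartlett score of Sputum Qualitative by Light microscopy"),
        value = 8L)),
    molecular = list(
      result = positivity_concept("positive"),
      organism = fx_concept("snomed", "990002001",
                            "Fixture respiratory virus (organism)"),
      assay = list(list(
        code = fx_concept("snomed", "9718006",
                          "Polymerase chain reaction analysis (procedure)"),
        value = quantity(24, "1")))),
    serology = list(
      test = fx_concept("loinc", "88603-6",
        "Adenovirus Ag [Presence] in Lower respiratory specimen by Immunoassay"),
      result = positivity_concept("positive"),
      antibody_quantity = quantity(12, "[arb'U]/mL"),
      avidity = list(value = fx_concept("snomed", "75540009",
                                        "High (qualifier value)"))),
    mdro_type = list(
      value = fx_concept("snomed", "726492000",
        "Carbapenem resistant Pseudomonas aeruginosa (organism)")),
    mrgn = list(value = fx_concept("loinc", "LA33216-5", "4MRGN")),
    resistance_mechanism = list(
      test = fx_concept("loinc", "92251-8",
        "Microorganism gene detected [Presence] by Molecular method"),
      result = positivity_concept("positive"),
      gene = list(name = "blaKPC-2", source = "NCBI",
                  identifier = "NG_049253")),
    virulence = list(
      test = fx_concept("loinc", "99008-8",
                        "Shiga toxin 1 [Presence] in Isolate"),
      result = detection_concept("detected"))
  )
  payload$id <- id
  payload$specimen <- "Specimen/sp-1"
  payload[names(extra)] <- extra
  new_observation(kind, payload)
}

make_body <- function(kind, ...) to_fhir(make_obs(kind, ...))$body

all_kinds <- function() observation_kinds()$kind

# Independent brute-force oracle for the MRGN rules: a direct transcription
# of the classification sentences, sharing no code with the implementation.
mrgn_oracle <- function(is_pa, groups, carbapenemase, neonatology) {
  if (carbapenemase) return("4MRGN")
  if (identical(groups[["carbapenems"]], "R") && !is_pa) return("4MRGN")
  n <- sum(groups == "R")
  if (n == 4) return("4MRGN")
  if (n == 3) return("3MRGN")
  if (n == 2 && neonatology) return("2MRGN")
  "none"
}

mrgn_grid <- function() {
  lv <- c("S", "I", "R", "NT")
  expand.grid(ureidopenicillins = lv, cephalosporins = lv, carbapenems = lv,
              fluoroquinolones = lv, carbapenemase = c(TRUE, FALSE),
              neonatology = c(TRUE, FALSE), pa = c(TRUE, FALSE),
              stringsAsFactors = FALSE)
}
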