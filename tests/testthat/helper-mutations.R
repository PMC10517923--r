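# Single-fault mutation harness: for every rule in the catalog, one valid
# fixture plus a mutation of exactly one checked element that must trigger
# that rule at the mutated path.

mutation_cases <- function() {
  cases <- list()
  case <- function(rule, path, body, siblings = NULL, exact = TRUE) {
    cases[[length(cases) + 1L]] <<- list(rule = rule, path = path,
                                         body = body, siblings = siblings,
                                         exact = exact)
  }

  b <- make_body("culture")
  b$category[[1]]$coding[[1]]$code <- "99999-9"
  case("cat-microbiology-category", "Observation.category", b)

  b <- make_body("culture")
  b$code$coding[[1]]$code <- "11111-1"
  case("culture-code-fixed", "Observation.code", b)

  b <- make_body("microscopy")
  b$code$coding[[1]]$code <- "999999"
  case("microscopy-code-fixed", "Observation.code", b)

  b <- make_body("molecular")
  b$code$coding[[1]]$code <- "11111-1"
  case("molecular-code-fixed", "Observation.code", b)

  b <- make_body("mdro_type")
  b$code$coding[[1]]$code <- "999999"
  case("mdro-code-fixed", "Observation.code", b)

  b <- make_body("mrgn")
  b$code$coding[[1]]$code <- "11111-1"
  case("mrgn-code-fixed", "Observation.code", b)

  b <- make_body("colony_count")
  b$code$coding[[1]]$code <- "11111-1"
  case("colony-code-vs", "Observation.code", b)

  b <- make_body("susceptibility")
  b$code$coding[[1]]$code <- "99006-6"   # genotyping method
  case("susc-code-vs", "Observation.code", b)

  b <- make_body("serology")
  b$code$coding[[1]]$code <- "11111-1"
  case("serology-code-vs", "Observation.code", b)

  b <- make_body("resistance_mechanism")
  b$code$coding[[1]]$code <- "88603-6"
  case("resistance-code-vs", "Observation.code", b)

  b <- make_body("virulence")
  b$code$coding[[1]]$code <- "88603-6"
  case("virulence-code-vs", "Observation.code", b)

  b <- to_fhir(make_obs("culture", organism = NULL))$body
  b$valueCodeableConcept$coding[[1]]$code <- "10828004"
  case("result-vs-mismatch", "Observation.valueCodeableConcept", b)

  b <- make_body("colony_count")
  b$valueCodeableConcept <- list(coding = list(list(
    system = "http://snomed.info/sct", code = "260347006")))
  case("colony-choice-exclusive", "Observation.value", b)

  b <- make_body("susceptibility")
  b$interpretation[[1]]$coding[[1]]$system <- "http://example.org/unknown"
  case("susc-interpretation-vs", "Observation.interpretation[0].coding[0].system", b)

  b <- make_body("susceptibility")
  b$interpretation[[1]]$coding[[1]]$version <- NULL
  case("susc-version-required", "Observation.interpretation[0].coding[0].version", b)

  b <- make_body("colony_count")
  b$valueQuantity$code <- "mg/L"   # wrong unit class for a count code
  case("ucum-unit", "Observation.valueQuantity", b)

  b <- make_body("culture")
  b$component[[1]]$valueCodeableConcept$coding[[1]]$code <- "990006002"
  case("organism-vs", "Observation.component[0].valueCodeableConcept", b)

  b <- make_body("culture")
  b$valueCodeableConcept$coding[[1]]$code <- "260415000"
  case("organism-requires-detected", "Observation.component", b)

  b <- make_body("microscopy")
  b$method$coding[[1]]$code <- "398545005"
  case("method-vs", "Observation.method", b)

  b <- make_body("microscopy")
  b$component[[2]]$code$coding[[1]]$code <- "99999-0"
  case("score-code-fixed", "Observation.component[1].code", b)

  b <- make_body("serology")
  avidity_at <- which(vapply(b$component, function(comp) {
    identical(comp$code$coding[[1]]$code, "77559007")
  }, logical(1)))
  b$component[[avidity_at]]$valueCodeableConcept$coding[[1]]$code <- "10828004"
  case("avidity-value-vs",
       sprintf("Observation.component[%d].valueCodeableConcept", avidity_at - 1L), b)

  b <- make_body("molecular")
  b$component[[2]]$code$coding[[1]]$code <- "77559007"
  case("assay-component-code", "Observation.component[1].code", b)

  b <- make_body("resistance_mechanism")
  b$component <- NULL
  case("gene-component-required", "Observation.component", b)

  b <- make_body("mdro_type")
  b$valueCodeableConcept$coding[[1]]$code <- "112283007"
  case("mdro-value-vs", "Observation.valueCodeableConcept", b)

  b <- make_body("mrgn")
  b$valueCodeableConcept$coding[[1]]$code <- "LA99999-9"
  case("mrgn-value-vs", "Observation.valueCodeableConcept", b)

  sib <- make_obs("virulence", id = "vf-9")
  culture <- link_culture_children(make_obs("culture"), "vf-9")
  b <- to_fhir(culture)$body
  case("hasmember-target-kind", "Observation.hasMember[0]", b,
       siblings = list(b, to_fhir(sib)$body))

  b <- to_fhir(microbiology_report("rep-m", "viral", character(0)))$body
  b$category[[1]]$coding <- b$category[[1]]$coding[1]  # study coding removed
  case("report-study-type", "DiagnosticReport.category", b)

  b <- make_body("virulence")
  b$meta$profile <- list("https://example.org/fhir/unknown")
  b$code$coding[[1]]$code <- "00000-0"
  case("profile-unrecognized", "Observation.meta.profile", b, exact = FALSE)

  b <- make_body("culture")
  b$funkyElement <- "x"
  case("unknown-element", "Observation.funkyElement", b)

  b <- make_body("microscopy")
  b$component <- c(b$component, list(list(
    code = list(coding = list(list(system = "http://snomed.info/sct",
                                   code = "84676004"))),
    valueCodeableConcept = list(coding = list(list(
      system = "http://snomed.info/sct", code = "260373001"))))))
  case("unknown-component", "Observation.component[2].code", b)

  cases
}
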