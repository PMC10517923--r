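test_that("the registry enumerates ten kinds over the four blocks", {
  reg <- observation_kinds()
  expect_equal(nrow(reg), 10)
  expect_setequal(unique(reg$block), model_blocks())
  expect_length(model_blocks(), 4)
  # detection-style vs positivity-style split
  expect_identical(reg$result_style[reg$kind %in%
                     c("culture", "microscopy", "virulence")],
                   rep("detection", 3))
  expect_identical(reg$result_style[reg$kind %in%
                     c("molecular", "serology", "resistance_mechanism")],
                   rep("positivity", 3))
})

test_that("every kind constructs from a valid payload and carries its fields", {
  for (kind in all_kinds()) {
    obs <- make_obs(kind)
    expect_s3_class(obs, "mf_observation")
    expect_s3_class(obs, paste0("mf_obs_", kind))
    expect_identical(obs$kind, kind)
    expect_identical(obs$specimen, "Specimen/sp-1")
  }
})

test_that("result value-set mix-ups are construction errors", {
  # a positivity code in a detection slot
  expect_error(make_obs("culture", result = positivity_concept("positive")),
               "result-vs-mismatch", class = "mf_invariant_error")
  # a detection code in a positivity slot
  expect_error(make_obs("molecular",
                        result = concept_ref("snomed", "260373001")),
               "result-vs-mismatch", class = "mf_invariant_error")
  expect_error(make_obs("virulence",
                        result = positivity_concept("negative")),
               "result-vs-mismatch", class = "mf_invariant_error")
})

test_that("organism components require a detected culture", {
  expect_error(make_obs("culture",
                        result = detection_concept("not-detected")),
               "organism-requires-detected", class = "mf_invariant_error")
  ok <- make_obs("culture", result = detection_concept("not-detected"),
                 organism = NULL)
  expect_length(ok$organism, 0)
  # organisms outside the value set are rejected wherever they appear
  expect_error(make_obs("culture",
                        organism = concept_ref("snomed", "990006002")),
               "organism-vs", class = "mf_invariant_error")
})

test_that("susceptibility interpretation demands scheme, category and version", {
  expect_error(make_obs("susceptibility", scheme_version = ""),
               "susc-version-required", class = "mf_invariant_error")
  expect_error(make_obs("susceptibility", interpretation = "SDD"),
               "susc-interpretation-vs", class = "mf_invariant_error")
  clsi <- make_obs("susceptibility", interpretation = "SDD", scheme = "CLSI",
                   scheme_version = "M100-Ed33")
  expect_identical(clsi$interpretation, "SDD")
  expect_error(make_obs("susceptibility", mic = quantity(10, "/mL")),
               "ucum-unit", class = "mf_invariant_error")
  # without an interpretation no version is needed
  plain <- make_obs("susceptibility", interpretation = NULL, scheme = NULL,
                    scheme_version = NULL)
  expect_null(plain$interpretation)
})

test_that("colony count enforces the quantity/semiquantitative choice", {
  expect_error(make_obs("colony_count", quantity = NULL),
               "colony-choice-exclusive", class = "mf_invariant_error")
  expect_error(
    make_obs("colony_count",
             semiquant = concept_ref("snomed", "260347006")),
    "colony-choice-exclusive", class = "mf_invariant_error")
  semi <- make_obs("colony_count", quantity = NULL,
                   semiquant = concept_ref("snomed", "260347006"))
  expect_null(semi$quantity)
  # the unit class must match the chosen code
  expect_error(make_obs("colony_count", quantity = quantity(5, "/g")),
               "ucum-unit", class = "mf_invariant_error")
})

test_that("restricted component codes are enforced", {
  expect_error(make_obs("microscopy",
                        score = list(code = concept_ref("loinc", "564-5"),
                                     value = 3)),
               "score-code-fixed", class = "mf_invariant_error")
  expect_error(make_obs("molecular", assay = list(list(
    code = concept_ref("snomed", "117259009"), value = quantity(1, "1")))),
    "assay-component-code", class = "mf_invariant_error")
  expect_error(make_obs("serology", avidity = list(
    value = concept_ref("snomed", "10828004"))),
    "avidity-value-vs", class = "mf_invariant_error")
  expect_error(make_obs("mdro_type",
                        value = concept_ref("snomed", "112283007")),
               "mdro-value-vs", class = "mf_invariant_error")
  expect_error(make_obs("mrgn", value = concept_ref("loinc", "LA0-0")),
               "mrgn-value-vs", class = "mf_invariant_error")
})

test_that("generic resistance codes demand a named gene", {
  expect_error(make_obs("resistance_mechanism", gene = NULL),
               "gene-component-required", class = "mf_invariant_error")
  specific <- make_obs("resistance_mechanism",
                       test = concept_ref("loinc", "72421-1"), gene = NULL)
  expect_null(specific$gene)
  expect_error(make_obs("resistance_mechanism",
                        gene = list(name = "x", source = "elsewhere",
                                    identifier = "y")),
               "gene-component-required", class = "mf_invariant_error")
})

test_that("culture member linking is guarded, ordered and duplicate-free", {
  culture <- make_obs("culture")
  linked <- link_culture_children(culture, "cc-1")
  expect_identical(linked$children, "cc-1")
  linked <- link_culture_children(linked, c("cc-1", "su-1"))
  expect_identical(linked$children, c("cc-1", "su-1"))
  negative <- make_obs("culture", result = detection_concept("not-detected"),
                       organism = NULL)
  expect_error(link_culture_children(negative, "cc-1"),
               class = "mf_invariant_error")
})

test_that("multiple organisms per culture are allowed", {
  obs <- make_obs("culture", organism = list(
    concept_ref("snomed", "112283007"), concept_ref("snomed", "56415008")))
  expect_length(obs$organism, 2)
})
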