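test_that("culture serializes with its fixed code, result and organism component", {
  body <- make_body("culture")
  expect_identical(body$resourceType, "Observation")
  expect_identical(body$code$coding[[1]]$code, "11475-1")
  expect_identical(body$code$coding[[1]]$system, "http://loinc.org")
  expect_identical(body$valueCodeableConcept$coding[[1]]$code, "260373001")
  expect_length(body$component, 1)
  expect_identical(body$component[[1]]$valueCodeableConcept$coding[[1]]$code,
                   "112283007")
  expect_identical(body$category[[1]]$coding[[1]]$code, "18725-2")
})

test_that("susceptibility carries the standard's version on the interpretation coding", {
  body <- make_body("susceptibility", scheme_version = "v13")
  coding <- body$interpretation[[1]]$coding[[1]]
  expect_identical(coding$version, "v13")
  expect_identical(coding$code, "R")
  expect_match(coding$system, "eucast")
  clsi <- make_body("susceptibility", scheme = "CLSI",
                    scheme_version = "M100", interpretation = "NS")
  expect_identical(clsi$interpretation[[1]]$coding[[1]]$system,
                   "http://terminology.hl7.org/CodeSystem/v3-ObservationInterpretation")
})

test_that("choice types are exclusive in the emitted JSON", {
  q <- make_body("colony_count")
  expect_false(is.null(q$valueQuantity))
  expect_null(q$valueCodeableConcept)
  s <- make_body("colony_count", quantity = NULL,
                 semiquant = concept_ref("snomed", "260347006"))
  expect_null(s$valueQuantity)
  expect_false(is.null(s$valueCodeableConcept))
})

test_that("round trip through FHIR JSON is the identity for all ten kinds", {
  for (kind in all_kinds()) {
    obs <- make_obs(kind)
    env <- to_fhir(obs)
    # through actual JSON text, not just the list tree
    parsed <- jsonlite::fromJSON(fhir_json(env), simplifyVector = FALSE)
    expect_identical(from_fhir(parsed), obs, label = kind)
  }
})

test_that("serialization is byte-stable and never emits extensions or bare codes", {
  for (kind in all_kinds()) {
    env <- to_fhir(make_obs(kind))
    json <- fhir_json(env)
    expect_identical(json, fhir_json(to_fhir(make_obs(kind))), label = kind)
    expect_false(grepl("\"extension\"", json), label = kind)
  }
  # every coding carries its system
  body <- make_body("molecular")
  walk <- function(x) {
    if (is.list(x)) {
      if (!is.null(x$code) && is.character(x$code) && is.null(x$system) &&
          !is.null(x$coding)) {
        fail("coding without system")
      }
      if (!is.null(names(x)) && "coding" %in% names(x)) {
        for (coding in x$coding) expect_true(nzchar(coding$system))
      }
      lapply(x, walk)
    }
    invisible(NULL)
  }
  walk(body)
})

test_that("dispatch falls back on fixed Observation.code values", {
  body <- make_body("molecular")
  body$meta <- NULL
  obs <- from_fhir(body)
  expect_identical(obs$kind, "molecular")
  expect_error(from_fhir(list(resourceType = "Patient")), "dispatch")
})

test_that("report bundles are internally consistent", {
  observations <- list(make_obs("culture", id = "o1"),
                       make_obs("colony_count", id = "o2"))
  report <- microbiology_report("rep1", "bacterial", c("o1", "o2"),
                                conclusion = "E. coli, high colony count")
  bundle <- to_report_bundle(report, observations)
  expect_identical(bundle$type, "collection")
  expect_length(bundle$entry, 3)
  dr <- bundle$entry[[1]]$resource
  codes <- unlist(lapply(dr$category[[1]]$coding, `[[`, "code"))
  expect_true(all(c("4341000179107", "92894-5") %in% codes))
  # every result reference resolves to an entry fullUrl
  urls <- vapply(bundle$entry, `[[`, character(1), "fullUrl")
  refs <- vapply(dr$result, `[[`, character(1), "reference")
  expect_true(all(refs %in% urls))
  expect_true(all(grepl("^urn:uuid:", urls)))
  expect_error(to_report_bundle(
    microbiology_report("rep2", "viral", "missing-id"), observations),
    "missing")
})

test_that("NDJSON writing and reading preserve resources", {
  envs <- lapply(all_kinds(), function(kind) to_fhir(make_obs(kind)))
  tf <- tempfile(fileext = ".ndjson")
  write_ndjson(envs, tf)
  back <- read_fhir_file(tf)
  expect_length(back, length(envs))
  expect_identical(back[[1]]$id, envs[[1]]$body$id)
  # a single-resource JSON file parses too
  tf2 <- tempfile(fileext = ".json")
  writeLines(fhir_json(envs[[1]], pretty = TRUE), tf2)
  expect_length(read_fhir_file(tf2), 1)
})
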