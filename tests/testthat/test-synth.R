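test_that("fixture regeneration is byte-identical to the bundled snapshots", {
  out <- tempfile()
  paths <- generate_snapshot_fixtures(out)
  for (name in c("snomed_mini.tsv", "loinc_mini.tsv")) {
    bundled <- system.file("extdata", name, package = "microfhir")
    expect_identical(readBin(file.path(out, name), "raw", 1e6),
                     readBin(bundled, "raw", 1e6), label = name)
  }
  # regenerating over the same directory is a no-op
  generate_snapshot_fixtures(out)
  expect_identical(readLines(paths[["snomed"]]),
                   readLines(system.file("extdata", "snomed_mini.tsv",
                                         package = "microfhir")))
})

test_that("the fixture graph wires the printed resistance chain and parts", {
  snaps <- default_snapshots()
  snomed <- snaps[[code_systems()[["snomed"]]]]
  expect_true("726492000" %in% descendants(snomed, "707497007"))
  expect_true("707497007" %in% descendants(snomed, "409793007"))
  loinc <- snaps[[code_systems()[["loinc"]]]]
  expect_identical(loinc$parts$property[loinc$parts$code == "18945-6"],
                   "Susc")
})

test_that("table generation is deterministic and covers every kind", {
  cfg <- synth_config(seed = 1, n_results = 60)
  a <- generate_lab_table(cfg)
  b <- generate_lab_table(cfg)
  expect_identical(a, b)
  expect_setequal(unique(a$kind), all_kinds())
  expect_identical(names(a),
                   c("patient_id", "isolate_id", "row_id", "block", "kind",
                     "test_code", "test_system", "result_code_or_value",
                     "unit", "interpretation", "scheme", "scheme_version",
                     "method_code", "organism_code", "flags"))
  # susceptibility rows always carry scheme and version
  susc <- a[a$kind == "susceptibility", ]
  expect_true(all(nzchar(susc$scheme)))
  expect_true(all(nzchar(susc$scheme_version)))
})

test_that("a zero positivity rate produces no detected or positive results", {
  cfg <- synth_config(seed = 2, n_results = 80, positivity_rate = 0)
  tab <- generate_lab_table(cfg)
  detection_kinds <- c("culture", "microscopy", "molecular", "serology",
                       "virulence", "resistance_mechanism")
  res <- tab$result_code_or_value[tab$kind %in% detection_kinds]
  expect_false(any(res %in% c("260373001", "10828004", "260408008")))
})

test_that("fully resistant panels classify 4MRGN for non-P.-aeruginosa isolates", {
  cfg <- synth_config(seed = 3, n_results = 60, resistance_rate = 1,
                      carbapenemase_rate = 0)
  tab <- generate_lab_table(cfg)
  susc <- tab[tab$kind == "susceptibility", ]
  expect_gt(nrow(susc), 0)
  groups_of <- function(rows) {
    flags <- lapply(rows$flags, microfhir:::parse_flags)
    stats::setNames(rows$interpretation,
                    vapply(flags, function(f) f$group, character(1)))
  }
  for (iso in unique(susc$isolate_id)) {
    rows <- susc[susc$isolate_id == iso, ]
    g <- groups_of(rows)[mrgn_groups()]
    species <- rows$organism_code[1]
    got <- mrgn_classify(species, g)$category
    want <- mrgn_oracle(species %in% c("52499004", "990001001"), g,
                        carbapenemase = FALSE, neonatology = FALSE)
    expect_identical(got, want, label = iso)
    if (!species %in% c("52499004", "990001001")) {
      expect_identical(got, "4MRGN", label = iso)
    }
  }
})

test_that("conversion conserves counts and collects row-level errors", {
  cfg <- synth_config(seed = 4, n_results = 50)
  tab <- generate_lab_table(cfg)
  res <- table_to_observations(tab)
  expect_length(res$observations, nrow(tab))
  expect_identical(nrow(res$errors), 0L)
  # a member row whose isolate has no culture row is a collected error
  orphan <- tab[tab$kind == "colony_count", ][1, ]
  orphan$isolate_id <- "ISO9999"
  res2 <- table_to_observations(rbind(tab, orphan))
  expect_match(res2$errors$message, "no preceding culture", all = FALSE)
  # an unknown kind is collected, not fatal
  bad <- tab[1, ]
  bad$kind <- "astrology"
  res3 <- table_to_observations(rbind(tab, bad))
  expect_match(res3$errors$message, "unknown observation kind", all = FALSE)
  expect_length(res3$observations, nrow(tab))
})

test_that("member rows are wired to their culture via hasMember", {
  cfg <- synth_config(seed = 5, n_results = 60)
  tab <- generate_lab_table(cfg)
  res <- table_to_observations(tab)
  cultures <- Filter(function(o) o$kind == "culture", res$observations)
  children <- unlist(lapply(cultures, `[[`, "children"))
  member_rows <- tab$row_id[tab$kind %in% c("colony_count", "susceptibility") &
                              tab$isolate_id %in% tab$isolate_id[
                                tab$kind == "culture" &
                                  tab$result_code_or_value == "260373001"]]
  expect_true(all(children %in% tab$row_id))
  expect_true(all(member_rows %in% children))
})

test_that("the full pipeline validates cleanly and is byte-deterministic", {
  cfg <- synth_config(seed = 11, n_results = 60)
  run <- function() {
    tab <- generate_lab_table(cfg)
    envs <- lapply(table_to_observations(tab)$observations, to_fhir)
    vapply(envs, fhir_json, character(1))
  }
  first <- run()
  expect_identical(first, run())
  bodies <- lapply(first, jsonlite::fromJSON, simplifyVector = FALSE)
  issues <- do.call(rbind, lapply(bodies, validate_resource,
                                  siblings = bodies))
  expect_identical(sum(issues$severity == "error"), 0L)
})

test_that("fault injection produces rows the validator flags", {
  cfg <- synth_config(seed = 12, n_results = 80, fault_rate = 0.4)
  tab <- generate_lab_table(cfg)
  expect_gt(sum(grepl("fault=", tab$flags)), 0)
  envs <- lapply(table_to_observations(tab)$observations, to_fhir)
  issues <- do.call(rbind, lapply(envs, validate_resource))
  expect_true(all(c("result-vs-mismatch", "susc-version-required") %in%
                    issues$rule_id[issues$severity == "error"]))
})

test_that("configuration invariants are enforced", {
  expect_error(synth_config(block_mix = c(culture = 1, molecular = 0.5,
                                          serology = 0,
                                          `further-properties` = 0)),
               "sum to 1")
  expect_error(synth_config(positivity_rate = 1.2), "rates")
})
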