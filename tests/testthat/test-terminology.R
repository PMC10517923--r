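snaps <- cached_snapshots()
snomed <- snaps[[code_systems()[["snomed"]]]]
loinc <- snaps[[code_systems()[["loinc"]]]]
catalog <- default_catalog()

test_that("snapshot loading honours the dialect contracts", {
  path <- system.file("extdata", "snomed_mini.tsv", package = "microfhir")
  n_rows <- length(readLines(path)) - 1L
  expect_equal(nrow(snomed$concepts), n_rows)
  expect_identical(snomed$dialect, "hierarchical")
  expect_identical(loinc$dialect, "tabular")
  expect_null(loinc$edges)
  expect_gt(nrow(snomed$edges), 0)
})

test_that("a cyclic is-a graph is rejected with a named cycle member", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("code\tdisplay\tparent_codes",
               "A\ta\tB", "B\tb\tA"), tf)
  expect_error(load_snapshot(tf, "hierarchical", "snomed"),
               "cycle.*(A|B)")
})

test_that("malformed snapshots fail with located parse errors", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("code\tdisplay\tparent_codes",
               "A\ta\t", "\tblank\t"), tf)
  expect_error(load_snapshot(tf, "hierarchical", "snomed"), "row 2")
  tf2 <- tempfile(fileext = ".tsv")
  writeLines(c("code\tdisplay", "A\ta"), tf2)
  expect_error(load_snapshot(tf2, "hierarchical", "snomed"), "parent_codes")
  expect_error(load_snapshot(tempfile(), "hierarchical", "snomed"),
               "not found")
})

test_that("descendants() follows strict vs descendant-or-self semantics", {
  d <- descendants(snomed, "410607006", include_self = FALSE)
  expect_false("410607006" %in% d)
  expect_true(all(c("112283007", "990001001", "726492000") %in% d))
  expect_true("410607006" %in%
                descendants(snomed, "410607006", include_self = TRUE))
  # leaves expand to nothing
  expect_identical(descendants(snomed, "112283007"), character(0))
  # the chained resistance subtree is fully reachable
  expect_true(all(c("707497007", "726492000") %in%
                    descendants(snomed, "409793007")))
  expect_error(descendants(snomed, "not-a-code"),
               class = "mf_unknown_concept")
})

test_that("descendants() agrees with an independent graph oracle on random DAGs", {
  skip_if_not_installed("igraph")
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(20:200, 1)
    codes <- sprintf("N%03d", seq_len(n))
    # random DAG: each node picks parents among earlier nodes
    parents <- lapply(seq_len(n), function(i) {
      if (i == 1) character(0) else {
        k <- sample(0:min(3, i - 1L), 1)
        sample(codes[seq_len(i - 1L)], k)
      }
    })
    tf <- tempfile(fileext = ".tsv")
    writeLines(c("code\tdisplay\tparent_codes",
                 paste(codes, codes,
                       vapply(parents, paste, character(1), collapse = "|"),
                       sep = "\t")), tf)
    snap <- load_snapshot(tf, "hierarchical", "snomed")
    edges <- snap$edges
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$parent, to = edges$child), vertices = codes)
    for (root in sample(codes, 5)) {
      got <- sort(descendants(snap, root))
      want <- sort(setdiff(
        names(igraph::subcomponent(g, root, mode = "out")), root))
      expect_identical(got, want)
    }
  }
})

test_that("extensional expansion is verbatim, duplicate-free and order-insensitive", {
  cc <- expand_valueset(catalog_vs(catalog, "colony-count-codes"), snaps)
  expect_setequal(cc$code, c("49223-1", "564-5", "38436-2", "20774-6"))
  expect_equal(nrow(cc), 4)
  dup <- valueset_def("urn:test:dup", "extensional", members = list(
    concept_ref("loinc", "564-5"), concept_ref("loinc", "49223-1"),
    concept_ref("loinc", "564-5")))
  expanded <- expand_valueset(dup, snaps)
  expect_equal(nrow(expanded), 2)
  expect_identical(expanded$code, sort(expanded$code))
})

test_that("organism expansion drops the five excluded kingdom subtrees", {
  org <- expand_valueset(catalog_vs(catalog, "organism"), snaps)
  expect_true(all(c("112283007", "52499004", "49872002", "84676004",
                    "414561005", "370570004") %in% org$code))
  excluded <- c("990005001", "990005002", "990006001", "990006002",
                "990007001", "990007002", "990008001", "990009001")
  expect_length(intersect(org$code, excluded), 0)
  expect_false("410607006" %in% org$code)  # strict-descendant include
})

test_that("tabular rules conjoin part constraints case-insensitively", {
  susc <- expand_valueset(catalog_vs(catalog, "susceptibility-tests"), snaps)
  expect_true("18945-6" %in% susc$code)
  expect_false("99006-6" %in% susc$code)    # genotyping method excluded
  expect_false("92253-4" %in% susc$code)    # property is not Susc
  mut <- expand_valueset(catalog_vs(catalog, "resistance-mutations"), snaps)
  expect_setequal(mut$code, c("72421-1", "99007-7"))
})

test_that("membership matches expansion without materializing it", {
  detection <- catalog_vs(catalog, "detection-result")
  expect_true(valueset_contains(detection,
                                concept_ref("snomed", "260373001"), snaps))
  expect_false(valueset_contains(detection,
                                 concept_ref("snomed", "10828004"), snaps))
  empty <- valueset_def("urn:test:empty", "extensional", members = list())
  expect_false(valueset_contains(empty, concept_ref("snomed", "260373001"),
                                 snaps))
  # unknown codes raise rather than silently reporting FALSE
  expect_error(
    valueset_contains(catalog_vs(catalog, "organism"),
                      concept_ref("snomed", "123123123"), snaps),
    class = "mf_unknown_concept")
})

test_that("contains() and expand() agree for every catalog VS and fixture concept", {
  concepts <- c(
    lapply(snomed$concepts$code, function(code) concept_ref("snomed", code)),
    lapply(loinc$concepts$code, function(code) concept_ref("loinc", code)))
  for (vs in catalog) {
    expanded <- expand_valueset(vs, snaps)
    keys <- paste(expanded$system, expanded$code)
    for (concept in concepts) {
      member <- tryCatch(valueset_contains(vs, concept, snaps),
                         mf_unknown_concept = function(e) NA)
      if (is.na(member)) next  # concept outside this rule's snapshot
      expect_identical(member,
                       paste(concept$system, concept$code) %in% keys,
                       label = sprintf("%s in %s", concept$code, vs$name))
    }
  }
})

test_that("exclusions dominate inclusions", {
  vs <- valueset_def("urn:test:excl", "intensional", rule = list(
    dialect = "hierarchical", system = "http://snomed.info/sct",
    include = list(list(op = "<<", code = "990006001"),
                   list(op = "<", code = "410607006")),
    exclude = "990006001"))
  out <- expand_valueset(vs, snaps)
  expect_false(any(c("990006001", "990006002") %in% out$code))
  expect_false(valueset_contains(vs, concept_ref("snomed", "990006002"),
                                 snaps))
})
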