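#' Validation rule catalog
#'
#' Stable enumeration of every rule the profile validator can emit, with the
#' profile table (or model source) each rule is compiled from. Rule ids are
#' part of the package interface and do not change between releases.
#'
#' @return `data.frame` with columns `rule_id`, `source`, `severity`,
#'   `description`.
#' @export
rule_catalog <- function() {
  r <- function(id, source, severity, description) {
    c(id, source, severity, description)
  }
  rows <- rbind(
    r("cat-microbiology-category", "Results", "error",
      "Observation.category must carry the fixed microbiology-studies coding 18725-2"),
    r("culture-code-fixed", "Table 1", "error",
      "culture detection code is fixed to LOINC 11475-1"),
    r("microscopy-code-fixed", "Table 4", "error",
      "microscopy code is fixed to SNOMED 117259009"),
    r("molecular-code-fixed", "Table 5", "error",
      "molecular detection code is fixed to LOINC 92253-4"),
    r("mdro-code-fixed", "Table 7", "error",
      "MDRO-type code is fixed to SNOMED 1285113001"),
    r("mrgn-code-fixed", "Table 8", "error",
      "MRGN classification code is fixed to LOINC 99780-9"),
    r("colony-code-vs", "Table 2", "error",
      "colony-count code must be one of the four colony-count LOINC codes"),
    r("susc-code-vs", "Table 3", "error",
      "susceptibility test must satisfy the phenotypic (Property Susc, not Genotyping) rule"),
    r("serology-code-vs", "Table 6", "error",
      "serology test must be the immunology procedure or a serology value-set code"),
    r("resistance-code-vs", "Table 9", "error",
      "resistance test must be a gene/mutation value-set code or a generic gene-detected code"),
    r("virulence-code-vs", "Table 10", "error",
      "virulence test must be in the virulence-factor value set"),
    r("result-vs-mismatch", "Tables 1/4/5/6/9/10", "error",
      "primary result must be drawn from the kind's result value set"),
    r("colony-choice-exclusive", "Table 2", "error",
      "exactly one of valueQuantity / valueCodeableConcept must be present"),
    r("susc-interpretation-vs", "Table 3", "error",
      "interpretation must be an EUCAST (S/I/R) or CLSI-style (S/SDD/I/R/NS) category with a recognized coding.system"),
    r("susc-version-required", "Table 3", "error",
      "interpretation coding must carry the standard's version string"),
    r("ucum-unit", "Tables 2/3", "error",
      "quantities must use a registered UCUM unit matching their context"),
    r("organism-vs", "Tables 1/4/5", "error",
      "organism components must lie in the organism hierarchy minus the excluded sub-groups"),
    r("organism-requires-detected", "Table 1", "error",
      "an organism component may only accompany a detected culture result"),
    r("method-vs", "Table 4", "error",
      "microscopy method must be an enumerated procedure or a staining method"),
    r("score-code-fixed", "Table 4", "error",
      "LOINC-coded microscopy components are restricted to the Bartlett and vaginosis scores"),
    r("avidity-value-vs", "Table 6", "error",
      "qualitative avidity is restricted to High/Low"),
    r("assay-component-code", "Table 5", "error",
      "molecular numeric components are restricted to nucleic-acid assay and PCR"),
    r("gene-component-required", "Table 9", "error",
      "generic gene-detected codes require a gene-name component"),
    r("mdro-value-vs", "Table 7", "error",
      "MDRO-type value must lie under a resistant-organism hierarchy"),
    r("mrgn-value-vs", "Table 8", "error",
      "MRGN value must be one of the three answer codes"),
    r("hasmember-target-kind", "Table 11", "error",
      "culture members must resolve to colony-count or susceptibility observations"),
    r("report-study-type", "Results", "error",
      "report category must carry the microbiology-report coding and one of the five study types"),
    r("profile-unrecognized", "-", "error",
      "resource cannot be dispatched to a known profile"),
    r("unknown-element", "-", "warning",
      "element not part of the profiled resource (open-world warning)"),
    r("unknown-component", "-", "warning",
      "component code not recognized for this observation kind")
  )
  data.frame(rule_id = rows[, 1], source = rows[, 2], severity = rows[, 3],
             description = rows[, 4], stringsAsFactors = FALSE)
}

new_issue_collector <- function() {
  issues <- list()
  list(
    add = function(severity, rule_id, path, message) {
      issues[[length(issues) + 1L]] <<- data.frame(
        severity = severity, rule_id = rule_id, path = path,
        message = message, stringsAsFactors = FALSE)
    },
    result = function() {
      if (!length(issues)) {
        return(data.frame(severity = character(0), rule_id = character(0),
                          path = character(0), message = character(0),
                          stringsAsFactors = FALSE))
      }
      out <- do.call(rbind, issues)
      out <- out[order(out$path, out$rule_id), , drop = FALSE]
      rownames(out) <- NULL
      out
    }
  )
}

cc_has_coding <- function(cc, system, code) {
  any(vapply(cc$coding %||% list(), function(coding) {
    identical(coding$system, system) && identical(coding$code, code)
  }, logical(1)))
}

vs_contains_safe <- function(vs, concept, snapshots) {
  tryCatch(valueset_contains(vs, concept, snapshots),
           mf_unknown_concept = function(e) NA)
}

#' Validate a FHIR resource against the microbiology profiles
#'
#' Checks a FHIR JSON resource (or an envelope produced by [to_fhir()])
#' against the fixed values, value-set bindings and structural constraints of
#' the profiled tables and returns the violations as structured issues — an
#' empty frame means the resource conforms to every applicable rule. Problems
#' are always reported, never raised. Only elements the profiles fix or bind
#' are checked; missing optional elements are not issues, and elements
#' outside the profile surface only as warnings.
#'
#' @param x Envelope or parsed resource tree.
#' @param snapshots,catalog Terminology context.
#' @param siblings Optional list of sibling envelopes/resources used to
#'   resolve `hasMember` references; when supplied, culture members must
#'   resolve to colony-count or susceptibility observations.
#' @return `data.frame` with columns `severity`, `rule_id`, `path`,
#'   `message`, deterministically sorted by path then rule id.
#' @export
validate_resource <- function(x, snapshots = cached_snapshots(),
                              catalog = default_catalog(), siblings = NULL) {
  env <- as_envelope(x)
  body <- env$body
  col <- new_issue_collector()
  if (identical(body$resourceType, "DiagnosticReport")) {
    validate_report_body(body, col)
    return(col$result())
  }
  if (!identical(body$resourceType, "Observation")) {
    col$add("error", "profile-unrecognized", "resourceType",
            paste0("unsupported resourceType ",
                   body$resourceType %||% "<missing>"))
    return(col$result())
  }
  kind <- tryCatch(dispatch_kind(body), error = function(e) NA_character_)
  if (is.na(kind)) {
    col$add("error", "profile-unrecognized", "Observation.meta.profile",
            "neither meta.profile nor Observation.code identify a known profile")
    return(col$result())
  }
  validate_common(body, kind, col)
  validator <- switch(kind,
    culture = validate_culture, colony_count = validate_colony,
    susceptibility = validate_susceptibility, microscopy = validate_microscopy,
    molecular = validate_molecular, serology = validate_serology,
    mdro_type = validate_mdro, mrgn = validate_mrgn,
    resistance_mechanism = validate_resistance, virulence = validate_virulence)
  validator(body, col, snapshots, catalog, siblings)
  col$result()
}

OBSERVATION_ELEMENTS <- c(
  "resourceType", "id", "meta", "identifier", "basedOn", "partOf", "status",
  "category", "code", "subject", "encounter", "effectiveDateTime",
  "effectivePeriod", "issued", "performer", "valueQuantity",
  "valueCodeableConcept", "valueString", "dataAbsentReason",
  "interpretation", "note", "bodySite", "method", "specimen", "device",
  "referenceRange", "hasMember", "derivedFrom", "component", "extension"
)

validate_common <- function(body, kind, col) {
  cats <- body$category %||% list()
  ok <- any(vapply(cats, cc_has_coding, logical(1),
                   resolve_system("loinc"), "18725-2"))
  if (!ok) {
    col$add("error", "cat-microbiology-category", "Observation.category",
            "category lacks the fixed LOINC 18725-2 microbiology coding")
  }
  if (!is.null(body$valueQuantity) && !is.null(body$valueCodeableConcept)) {
    col$add("error", "colony-choice-exclusive", "Observation.value",
            "valueQuantity and valueCodeableConcept are alternatives")
  }
  extra <- setdiff(names(body), OBSERVATION_ELEMENTS)
  for (el in extra) {
    col$add("warning", "unknown-element", paste0("Observation.", el),
            paste0("element '", el, "' is not part of the profiled resource"))
  }
  invisible(NULL)
}

check_fixed_code <- function(body, col, rule, system, code) {
  if (!cc_has_coding(body$code %||% list(), resolve_system(system), code)) {
    col$add("error", rule, "Observation.code.coding[0].code",
            paste0("code is fixed to ", code))
    FALSE
  } else TRUE
}

check_result_vs <- function(body, col, style, catalog) {
  cc <- body$valueCodeableConcept
  if (is.null(cc)) return(invisible(NULL))
  vs_name <- if (style == "detection") "detection-result" else "positivity-result"
  concept <- tryCatch(cc_concept(cc), error = function(e) NULL)
  ok <- !is.null(concept) &&
    valueset_contains(catalog_vs(default_catalog(), vs_name), concept)
  if (!ok) {
    col$add("error", "result-vs-mismatch",
            "Observation.valueCodeableConcept.coding[0].code",
            paste0("result is not in the ", style, " value set"))
  }
  invisible(NULL)
}

check_organism_components <- function(body, col, snapshots, catalog) {
  comps <- body$component %||% list()
  for (i in seq_along(comps)) {
    if (!identical(component_code(comps[[i]]), "410607006")) next
    path <- sprintf("Observation.component[%d].valueCodeableConcept", i - 1L)
    concept <- tryCatch(cc_concept(comps[[i]]$valueCodeableConcept),
                        error = function(e) NULL)
    ok <- if (is.null(concept)) FALSE else {
      vs_contains_safe(catalog_vs(catalog, "organism"), concept, snapshots)
    }
    if (is.na(ok)) {
      col$add("error", "organism-vs", path,
              paste0("organism code ", concept$code,
                     " is unknown to the terminology snapshot"))
    } else if (!ok) {
      col$add("error", "organism-vs", path,
              "organism is outside the organism value set")
    }
  }
  invisible(NULL)
}

check_quantity_unit <- function(q, path, context, col) {
  unit <- q$code %||% q$unit
  ok <- !is.null(unit) && unit %in% ucum_units(context)
  if (!ok) {
    col$add("error", "ucum-unit", paste0(path, ".code"),
            paste0("unit '", unit %||% "<missing>",
                   "' is not a registered UCUM unit for this context"))
  }
  invisible(NULL)
}

validate_culture <- function(body, col, snapshots, catalog, siblings) {
  check_fixed_code(body, col, "culture-code-fixed", "loinc", "11475-1")
  check_result_vs(body, col, "detection", catalog)
  check_organism_components(body, col, snapshots, catalog)
  has_organism <- any(vapply(body$component %||% list(), function(comp) {
    identical(component_code(comp), "410607006")
  }, logical(1)))
  value_code <- tryCatch(body$valueCodeableConcept$coding[[1]]$code,
                         error = function(e) NULL)
  if (has_organism && !identical(value_code, DETECTION_CODES[["detected"]])) {
    col$add("error", "organism-requires-detected", "Observation.component",
            "organism component present but the culture result is not 'detected'")
  }
  if (!is.null(siblings) && length(body$hasMember %||% list())) {
    kinds <- sibling_kinds(siblings)
    members <- body$hasMember
    for (i in seq_along(members)) {
      id <- strip_obs_ref(members[[i]]$reference %||% "")
      kind <- kinds[[id]] %||% NA_character_
      if (is.na(kind) || !kind %in% c("colony_count", "susceptibility")) {
        col$add("error", "hasmember-target-kind",
                sprintf("Observation.hasMember[%d]", i - 1L),
                if (is.na(kind)) {
                  paste0("member reference '", id, "' does not resolve")
                } else {
                  paste0("member '", id, "' is a ", kind,
                         " observation, not a colony count or susceptibility test")
                })
      }
    }
  }
}

sibling_kinds <- function(siblings) {
  out <- list()
  for (s in siblings) {
    b <- as_envelope(s)$body
    if (!identical(b$resourceType, "Observation")) next
    kind <- tryCatch(dispatch_kind(b), error = function(e) NA_character_)
    if (!is.null(b$id)) out[[b$id]] <- kind
  }
  out
}

validate_colony <- function(body, col, snapshots, catalog, siblings) {
  concept <- tryCatch(cc_concept(body$code), error = function(e) NULL)
  ok <- !is.null(concept) &&
    valueset_contains(catalog_vs(catalog, "colony-count-codes"), concept)
  if (!ok) {
    col$add("error", "colony-code-vs", "Observation.code.coding[0].code",
            "code is not one of the four colony-count codes")
  }
  has_q <- !is.null(body$valueQuantity)
  has_cc <- !is.null(body$valueCodeableConcept)
  if (has_q == has_cc) {
    col$add("error", "colony-choice-exclusive", "Observation.value",
            "exactly one of valueQuantity / valueCodeableConcept is required")
  }
  if (has_q && !has_cc && !is.null(concept) && ok) {
    check_quantity_unit(body$valueQuantity, "Observation.valueQuantity",
                        concept$code, col)
  }
  if (has_cc && !has_q) {
    sq <- tryCatch(cc_concept(body$valueCodeableConcept),
                   error = function(e) NULL)
    semi_ok <- !is.null(sq) &&
      valueset_contains(catalog_vs(catalog, "semiquantitative-result"), sq)
    if (!semi_ok) {
      col$add("error", "result-vs-mismatch",
              "Observation.valueCodeableConcept.coding[0].code",
              "value is not a semiquantitative result concept")
    }
  }
}

validate_susceptibility <- function(body, col, snapshots, catalog, siblings) {
  concept <- tryCatch(cc_concept(body$code), error = function(e) NULL)
  ok <- if (is.null(concept)) FALSE else {
    vs_contains_safe(catalog_vs(catalog, "susceptibility-tests"), concept,
                     snapshots)
  }
  if (is.na(ok) || !ok) {
    col$add("error", "susc-code-vs", "Observation.code.coding[0].code",
            "code does not satisfy the phenotypic susceptibility-test rule")
  }
  if (!is.null(body$valueQuantity)) {
    check_quantity_unit(body$valueQuantity, "Observation.valueQuantity",
                        "mic", col)
  }
  interps <- body$interpretation %||% list()
  for (i in seq_along(interps)) {
    coding <- tryCatch(interps[[i]]$coding[[1]], error = function(e) NULL)
    base <- sprintf("Observation.interpretation[%d].coding[0]", i - 1L)
    scheme <- if (identical(coding$system, resolve_system("eucast"))) {
      "EUCAST"
    } else if (identical(coding$system, resolve_system("hl7_interp"))) {
      "CLSI"
    } else NA_character_
    if (is.na(scheme)) {
      col$add("error", "susc-interpretation-vs", paste0(base, ".system"),
              "interpretation coding.system identifies neither the EUCAST nor the CLSI-style category system")
    } else if (!identical(coding$code %||% "", "") &&
               !coding$code %in% SCHEME_SETS[[scheme]]) {
      col$add("error", "susc-interpretation-vs", paste0(base, ".code"),
              paste0("'", coding$code, "' is not a ", scheme, " category"))
    }
    if (is.null(coding$version) || !nzchar(coding$version)) {
      col$add("error", "susc-version-required", paste0(base, ".version"),
              "the susceptibility standard's version is mandatory")
    }
  }
}

validate_microscopy <- function(body, col, snapshots, catalog, siblings) {
  check_fixed_code(body, col, "microscopy-code-fixed", "snomed", "117259009")
  check_result_vs(body, col, "detection", catalog)
  if (!is.null(body$method)) {
    m <- tryCatch(cc_concept(body$method), error = function(e) NULL)
    ok <- !is.null(m) &&
      (valueset_contains(catalog_vs(catalog, "microscopy-methods"), m) ||
         isTRUE(vs_contains_safe(catalog_vs(catalog, "staining-methods"), m,
                                 snapshots)))
    if (!ok) {
      col$add("error", "method-vs", "Observation.method.coding[0].code",
              "method is neither an enumerated microscopy procedure nor a staining method")
    }
  }
  check_organism_components(body, col, snapshots, catalog)
  comps <- body$component %||% list()
  for (i in seq_along(comps)) {
    coding <- tryCatch(comps[[i]]$code$coding[[1]], error = function(e) NULL)
    if (is.null(coding)) next
    path <- sprintf("Observation.component[%d].code.coding[0].code", i - 1L)
    if (identical(coding$system, resolve_system("loinc"))) {
      # the only LOINC-coded microscopy components are the two scores
      if (!coding$code %in% SCORE_CODES) {
        col$add("error", "score-code-fixed", path,
                "LOINC microscopy components are restricted to the Bartlett and vaginosis scores")
      }
    } else if (!coding$code %in% c("410607006",
                                   LOCAL_COMPONENTS$microscopy_quantity[1])) {
      col$add("warning", "unknown-component", path,
              paste0("component code ", coding$code, " not recognized"))
    }
  }
}

validate_molecular <- function(body, col, snapshots, catalog, siblings) {
  check_fixed_code(body, col, "molecular-code-fixed", "loinc", "92253-4")
  check_result_vs(body, col, "positivity", catalog)
  check_organism_components(body, col, snapshots, catalog)
  comps <- body$component %||% list()
  for (i in seq_along(comps)) {
    coding <- tryCatch(comps[[i]]$code$coding[[1]], error = function(e) NULL)
    if (is.null(coding)) next
    path <- sprintf("Observation.component[%d].code.coding[0].code", i - 1L)
    if (identical(coding$system, resolve_system("snomed"))) {
      if (!coding$code %in% c("410607006", ASSAY_CODES)) {
        col$add("error", "assay-component-code", path,
                "molecular components are restricted to the organism, nucleic-acid assay and PCR codes")
      }
    } else {
      col$add("warning", "unknown-component", path,
              paste0("component code ", coding$code, " not recognized"))
    }
  }
}

validate_serology <- function(body, col, snapshots, catalog, siblings) {
  concept <- tryCatch(cc_concept(body$code), error = function(e) NULL)
  ok <- !is.null(concept) &&
    ((identical(concept$system, resolve_system("snomed")) &&
        identical(concept$code, SEROLOGY_PROC_CODE)) ||
       valueset_contains(catalog_vs(catalog, "serology-tests"), concept))
  if (!ok) {
    col$add("error", "serology-code-vs", "Observation.code.coding[0].code",
            "test is neither the immunology procedure nor a serology value-set code")
  }
  check_result_vs(body, col, "positivity", catalog)
  comps <- body$component %||% list()
  for (i in seq_along(comps)) {
    code <- tryCatch(component_code(comps[[i]]), error = function(e) NULL)
    if (identical(code, "77559007") &&
        !is.null(comps[[i]]$valueCodeableConcept)) {
      v <- tryCatch(cc_concept(comps[[i]]$valueCodeableConcept),
                    error = function(e) NULL)
      if (is.null(v) || !v$code %in% AVIDITY_VALUE_CODES) {
        col$add("error", "avidity-value-vs",
                sprintf("Observation.component[%d].valueCodeableConcept", i - 1L),
                "qualitative avidity is restricted to High/Low")
      }
    }
  }
}

validate_mdro <- function(body, col, snapshots, catalog, siblings) {
  check_fixed_code(body, col, "mdro-code-fixed", "snomed", "1285113001")
  cc <- body$valueCodeableConcept
  if (!is.null(cc)) {
    v <- tryCatch(cc_concept(cc), error = function(e) NULL)
    ok <- if (is.null(v)) FALSE else {
      vs_contains_safe(catalog_vs(catalog, "mdro-type"), v, snapshots)
    }
    if (is.na(ok) || !ok) {
      col$add("error", "mdro-value-vs",
              "Observation.valueCodeableConcept.coding[0].code",
              "value is not under a resistant-organism hierarchy")
    }
  }
}

validate_mrgn <- function(body, col, snapshots, catalog, siblings) {
  check_fixed_code(body, col, "mrgn-code-fixed", "loinc", "99780-9")
  cc <- body$valueCodeableConcept
  if (!is.null(cc)) {
    v <- tryCatch(cc_concept(cc), error = function(e) NULL)
    if (is.null(v) || !v$code %in% MRGN_ANSWERS) {
      col$add("error", "mrgn-value-vs",
              "Observation.valueCodeableConcept.coding[0].code",
              "value must be one of the three MRGN answer codes")
    }
  }
}

validate_resistance <- function(body, col, snapshots, catalog, siblings) {
  concept <- tryCatch(cc_concept(body$code), error = function(e) NULL)
  generic <- !is.null(concept) && concept$code %in% GENERIC_GENE_CODES
  ok <- !is.null(concept) && (generic ||
    valueset_contains(catalog_vs(catalog, "resistance-genes"), concept) ||
    isTRUE(vs_contains_safe(catalog_vs(catalog, "resistance-mutations"),
                            concept, snapshots)))
  if (!ok) {
    col$add("error", "resistance-code-vs", "Observation.code.coding[0].code",
            "code is not a resistance gene/mutation test")
  }
  check_result_vs(body, col, "positivity", catalog)
  if (generic) {
    has_gene <- any(vapply(body$component %||% list(), function(comp) {
      identical(tryCatch(component_code(comp), error = function(e) ""),
                LOCAL_COMPONENTS$gene[1])
    }, logical(1)))
    if (!has_gene) {
      col$add("error", "gene-component-required", "Observation.component",
              "generic gene-detected codes require a gene-name component")
    }
  }
}

validate_virulence <- function(body, col, snapshots, catalog, siblings) {
  concept <- tryCatch(cc_concept(body$code), error = function(e) NULL)
  ok <- !is.null(concept) &&
    valueset_contains(catalog_vs(catalog, "virulence-tests"), concept)
  if (!ok) {
    col$add("error", "virulence-code-vs", "Observation.code.coding[0].code",
            "code is not in the virulence-factor value set")
  }
  check_result_vs(body, col, "detection", catalog)
}

REPORT_ELEMENTS <- c("resourceType", "id", "meta", "identifier", "basedOn",
                     "status", "category", "code", "subject", "encounter",
                     "effectiveDateTime", "issued", "performer", "specimen",
                     "result", "conclusion", "conclusionCode", "extension")

validate_report_body <- function(body, col) {
  cats <- body$category %||% list()
  has_report_type <- any(vapply(cats, cc_has_coding, logical(1),
                                resolve_system("snomed"), "4341000179107"))
  study <- character(0)
  for (cc in cats) {
    for (coding in cc$coding %||% list()) {
      if (identical(coding$system, resolve_system("loinc")) &&
          coding$code %in% STUDY_TYPES) {
        study <- c(study, coding$code)
      }
    }
  }
  if (!has_report_type || length(study) != 1L) {
    col$add("error", "report-study-type", "DiagnosticReport.category",
            "category must carry the microbiology-report coding plus exactly one of the five study-type codes")
  }
  extra <- setdiff(names(body), REPORT_ELEMENTS)
  for (el in extra) {
    col$add("warning", "unknown-element", paste0("DiagnosticReport.", el),
            paste0("element '", el, "' is not part of the profiled resource"))
  }
}

#' Render issues as an OperationOutcome-shaped object
#'
#' @param issues Data frame from [validate_resource()].
#' @return Named list shaped like a FHIR OperationOutcome resource.
#' @export
issues_to_operation_outcome <- function(issues) {
  list(
    resourceType = "OperationOutcome",
    issue = lapply(seq_len(nrow(issues)), function(i) {
      list(severity = issues$severity[i], code = "invariant",
           details = list(text = paste0("[", issues$rule_id[i], "] ",
                                        issues$message[i])),
           expression = list(issues$path[i]))
    })
  )
}
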