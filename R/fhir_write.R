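# --- small JSON building blocks -------------------------------------------

coding_of <- function(concept, version = NULL) {
  out <- list(system = concept$system, code = concept$code)
  if (!is.null(concept$display)) out$display <- concept$display
  if (!is.null(version)) out$version <- version
  out
}

codeable <- function(..., version = NULL) {
  concepts <- list(...)
  list(coding = lapply(concepts, coding_of, version = version))
}

quantity_json <- function(q) {
  list(value = q$value, unit = q$unit,
       system = resolve_system("ucum"), code = q$unit)
}

local_concept <- function(code, display) concept_ref("local", code, display)

LOCAL_COMPONENTS <- list(
  microscopy_quantity = c("microscopy-quantity", "Quantity of microorganisms seen"),
  antigen = c("antigen-quantity", "Antigen test numerical result"),
  antibody = c("antibody-quantity", "Antibody test numerical result"),
  gene = c("gene-name", "Resistance gene or mutation name")
)

local_component <- function(key) {
  def <- LOCAL_COMPONENTS[[key]]
  local_concept(def[1], def[2])
}

ORGANISM_COMPONENT_CODE <- function() {
  concept_ref("snomed", "410607006", "Organism (organism)")
}

component_cc <- function(code_concept, value_concept) {
  list(code = codeable(code_concept),
       valueCodeableConcept = codeable(value_concept))
}

component_q <- function(code_concept, q) {
  list(code = codeable(code_concept), valueQuantity = quantity_json(q))
}

# --- resource envelope -----------------------------------------------------

#' Wrap a FHIR resource body
#'
#' @param resource_type `"Observation"` or `"DiagnosticReport"`.
#' @param profile_url Canonical profile URL asserted in `meta.profile`.
#' @param body Named list representing the JSON resource tree.
#' @return Object of class `mf_envelope`.
#' @export
resource_envelope <- function(resource_type, profile_url, body) {
  stopifnot(resource_type %in% c("Observation", "DiagnosticReport"))
  if (!identical(body$resourceType, resource_type)) {
    stop("body.resourceType must equal resource_type", call. = FALSE)
  }
  if (!profile_url %in% unlist(body$meta$profile)) {
    stop("body.meta.profile must contain the profile url", call. = FALSE)
  }
  structure(list(resource_type = resource_type, profile_url = profile_url,
                 body = body),
            class = "mf_envelope")
}

#' @export
print.mf_envelope <- function(x, ...) {
  cat(sprintf("<FHIR %s (%s)>\n", x$resource_type, x$profile_url))
  invisible(x)
}

# --- writer ----------------------------------------------------------------

#' Serialize an observation to FHIR R4
#'
#' Maps a typed observation onto a FHIR R4 Observation resource: the test
#' onto `code`, the primary result onto `value[x]` (CodeableConcept or
#' Quantity, never both), additional results onto `component[]`, the
#' susceptibility category onto `interpretation` with the standard's version
#' in `coding.version`, the method onto `method`, culture children onto
#' `hasMember`, and the fixed microbiology category coding onto `category`.
#' No extensions are used. Total for valid input.
#'
#' @param x An `mf_observation`.
#' @param ... Unused.
#' @return An [resource_envelope()].
#' @export
to_fhir <- function(x, ...) UseMethod("to_fhir")

#' @export
to_fhir.mf_observation <- function(x, ...) {
  body <- list(
    resourceType = "Observation",
    id = x$id,
    meta = list(profile = list(profile_url(x$kind))),
    status = "final",
    category = list(codeable(CATEGORY_MICRO()))
  )
  if (!is.null(x$specimen)) body$specimen <- list(reference = x$specimen)
  body <- c(body, switch(x$kind,
    culture = fhir_culture(x),
    colony_count = fhir_colony(x),
    susceptibility = fhir_susceptibility(x),
    microscopy = fhir_microscopy(x),
    molecular = fhir_molecular(x),
    serology = fhir_serology(x),
    mdro_type = list(code = codeable(concept_ref("snomed", "1285113001",
      "Type of antimicrobial resistant organism (observable entity)")),
      valueCodeableConcept = codeable(x$value)),
    mrgn = list(code = codeable(concept_ref("loinc", "99780-9",
      "Multidrug resistant Gram-negative organism classification [Type]")),
      valueCodeableConcept = codeable(x$value)),
    resistance_mechanism = fhir_resistance(x),
    virulence = list(code = codeable(x$test),
                     valueCodeableConcept = codeable(x$result))
  ))
  resource_envelope("Observation", profile_url(x$kind), body)
}

organism_components <- function(organism) {
  lapply(organism, function(o) component_cc(ORGANISM_COMPONENT_CODE(), o))
}

fhir_culture <- function(x) {
  out <- list(
    code = codeable(concept_ref("loinc", "11475-1",
                                "Microorganism identified in Specimen by Culture")),
    valueCodeableConcept = codeable(x$result)
  )
  comps <- organism_components(x$organism)
  if (length(comps)) out$component <- comps
  if (length(x$children)) {
    out$hasMember <- lapply(x$children, function(id) {
      list(reference = paste0("Observation/", id))
    })
  }
  out
}

fhir_colony <- function(x) {
  out <- list(code = codeable(x$code))
  if (!is.null(x$quantity)) {
    out$valueQuantity <- quantity_json(x$quantity)
  } else {
    out$valueCodeableConcept <- codeable(x$semiquant)
  }
  out
}

scheme_system <- function(scheme) {
  switch(scheme, EUCAST = resolve_system("eucast"),
         CLSI = resolve_system("hl7_interp"))
}

fhir_susceptibility <- function(x) {
  out <- list(code = codeable(x$agent))
  if (!is.null(x$mic)) out$valueQuantity <- quantity_json(x$mic)
  if (!is.null(x$interpretation)) {
    out$interpretation <- list(list(coding = list(
      list(system = scheme_system(x$scheme), code = x$interpretation,
           version = x$scheme_version)
    )))
  }
  if (!is.null(x$method)) out$method <- codeable(x$method)
  out
}

fhir_microscopy <- function(x) {
  out <- list(
    code = codeable(concept_ref("snomed", "117259009", "Microscopy (procedure)")),
    valueCodeableConcept = codeable(x$result),
    method = codeable(x$method)
  )
  comps <- organism_components(x$organism)
  if (!is.null(x$score)) {
    comps <- c(comps, list(component_q(x$score$code,
                                       quantity(x$score$value, "1"))))
  }
  if (!is.null(x$quantity)) {
    comps <- c(comps, list(component_q(local_component("microscopy_quantity"),
                                       x$quantity)))
  }
  if (!is.null(x$semiquant)) {
    comps <- c(comps, list(component_cc(local_component("microscopy_quantity"),
                                        x$semiquant)))
  }
  if (length(comps)) out$component <- comps
  if (!is.null(x$morphology)) out$note <- list(list(text = x$morphology))
  out
}

fhir_molecular <- function(x) {
  out <- list(
    code = codeable(concept_ref("loinc", "92253-4",
      "Microorganism identified in Isolate or Specimen by Molecular genetics method")),
    valueCodeableConcept = codeable(x$result)
  )
  comps <- organism_components(x$organism)
  comps <- c(comps, lapply(x$assay, function(a) component_q(a$code, a$value)))
  if (length(comps)) out$component <- comps
  out
}

fhir_serology <- function(x) {
  out <- list(code = codeable(x$test),
              valueCodeableConcept = codeable(x$result))
  comps <- list()
  if (!is.null(x$antigen_quantity)) {
    comps <- c(comps, list(component_q(local_component("antigen"),
                                       x$antigen_quantity)))
  }
  if (!is.null(x$antibody_quantity)) {
    comps <- c(comps, list(component_q(local_component("antibody"),
                                       x$antibody_quantity)))
  }
  if (!is.null(x$avidity)) {
    avidity_code <- concept_ref("snomed", "77559007",
                                "Immunologic avidity, function (observable entity)")
    v <- x$avidity$value
    comps <- c(comps, list(
      if (is_quantity(v)) component_q(avidity_code, v)
      else component_cc(avidity_code, v)
    ))
  }
  if (length(comps)) out$component <- comps
  out
}

fhir_resistance <- function(x) {
  out <- list(code = codeable(x$test),
              valueCodeableConcept = codeable(x$result))
  if (!is.null(x$gene)) {
    gene_system <- if (x$gene$source == "NCBI") resolve_system("ncbi") else
      resolve_system("ebi")
    out$component <- list(list(
      code = codeable(local_component("gene")),
      valueCodeableConcept = list(coding = list(
        list(system = gene_system, code = x$gene$identifier,
             display = x$gene$name)
      ))
    ))
  }
  out
}

# --- report / bundle -------------------------------------------------------

# Deterministic urn:uuid derived from a string id (md5-based, stable).
mf_urn <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  h <- unname(tools::md5sum(tf))
  paste0("urn:uuid:", substr(h, 1, 8), "-", substr(h, 9, 12), "-",
         substr(h, 13, 16), "-", substr(h, 17, 20), "-", substr(h, 21, 32))
}

report_body <- function(report) {
  study <- STUDY_TYPES[STUDY_TYPES == report$category]
  body <- list(
    resourceType = "DiagnosticReport",
    id = report$id,
    meta = list(profile = list(REPORT_PROFILE_URL)),
    status = "final",
    code = codeable(CATEGORY_MICRO()),
    # one CodeableConcept carrying both the report-type coding and the
    # study-type coding
    category = list(list(coding = list(
      coding_of(concept_ref("snomed", "4341000179107",
                            "Microbiology report (record artifact)")),
      coding_of(concept_ref("loinc", report$category,
                            paste0("Microbiology - ", names(study),
                                   " studies (set)")))
    ))),
    result = lapply(report$results, function(id) {
      list(reference = paste0("Observation/", id))
    })
  )
  if (!is.null(report$conclusion)) body$conclusion <- report$conclusion
  body
}

#' @export
to_fhir.mf_report <- function(x, ...) {
  resource_envelope("DiagnosticReport", REPORT_PROFILE_URL, report_body(x))
}

#' Build a collection Bundle for a report
#'
#' Serializes a diagnostic report plus the observations it references into a
#' FHIR Bundle of type `collection`. Entries are addressed with deterministic
#' `urn:uuid` full URLs derived from the resource ids, and the report's
#' `result[]` references use the same URNs so the bundle is internally
#' consistent.
#'
#' @param report An [microbiology_report()].
#' @param observations List of `mf_observation` covering (at least) every id
#'   in `report$results`; a dangling reference is an error.
#' @return Named list representing the Bundle JSON tree.
#' @export
to_report_bundle <- function(report, observations) {
  stopifnot(inherits(report, "mf_report"))
  ids <- vapply(observations, `[[`, character(1), "id")
  missing_ids <- setdiff(report$results, ids)
  if (length(missing_ids)) {
    stop("report references missing observation(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  body <- report_body(report)
  body$result <- lapply(report$results, function(id) {
    list(reference = mf_urn(paste0("Observation/", id)))
  })
  entries <- c(
    list(list(fullUrl = mf_urn(paste0("DiagnosticReport/", report$id)),
              resource = body)),
    lapply(observations, function(o) {
      list(fullUrl = mf_urn(paste0("Observation/", o$id)),
           resource = to_fhir(o)$body)
    })
  )
  list(resourceType = "Bundle", type = "collection", entry = entries)
}

# --- canonical JSON --------------------------------------------------------

canonicalize <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && any(nzchar(names(x)))) {
      x <- x[order(names(x))]
    }
    lapply(x, canonicalize)
  } else {
    x
  }
}

#' Canonical FHIR JSON text
#'
#' Serializes an envelope (or a raw resource/Bundle tree) to a canonical JSON
#' string: object keys sorted, scalars unboxed, full numeric precision.
#' Serializing the same object twice is byte-identical.
#'
#' @param x An `mf_envelope` or a named list (resource tree).
#' @param pretty Pretty-print?
#' @return Length-1 character (JSON).
#' @export
fhir_json <- function(x, pretty = FALSE) {
  body <- if (inherits(x, "mf_envelope")) x$body else x
  as.character(jsonlite::toJSON(canonicalize(body), auto_unbox = TRUE,
                                digits = NA, null = "null", pretty = pretty))
}

#' Write resources as NDJSON
#'
#' @param x List of envelopes (or resource trees).
#' @param path Output file; one canonical-JSON resource per line.
#' @return Invisibly, `path`.
#' @export
write_ndjson <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(vapply(x, fhir_json, character(1)), con, sep = "\n",
             useBytes = TRUE)
  invisible(path)
}

#' Read resources from JSON or NDJSON
#'
#' `read_fhir_file()` accepts a file holding a single resource, a Bundle
#' (entries are unpacked), or NDJSON (one resource per line).
#'
#' @param path Input file.
#' @return List of parsed resource trees (named lists).
#' @export
read_fhir_file <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  txt <- paste(lines, collapse = "\n")
  parse_one <- function(s) jsonlite::fromJSON(s, simplifyVector = FALSE)
  bodies <- if (length(lines) > 1L && all(grepl("^\\s*\\{", lines[nzchar(lines)])) &&
                !grepl("^\\s*\\{\\s*$", lines[1])) {
    lapply(lines[nzchar(lines)], parse_one)
  } else {
    list(parse_one(txt))
  }
  out <- list()
  for (b in bodies) {
    if (identical(b$resourceType, "Bundle")) {
      out <- c(out, lapply(b$entry, `[[`, "resource"))
    } else {
      out <- c(out, list(b))
    }
  }
  out
}
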