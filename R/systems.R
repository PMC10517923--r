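#' Registered code-system URIs
#'
#' Canonical URIs for the code systems a microbiology result may reference:
#' SNOMED CT, LOINC, UCUM, the HL7 v3 ObservationInterpretation table used for
#' the five-value CLSI-style susceptibility categories, a self-defined EUCAST
#' susceptibility-category code system (EUCAST does not publish one), a small
#' self-defined component code system for sub-results that have no published
#' component code, and the NCBI / EMBL-EBI gene databases used to name
#' resistance genes.
#'
#' @return Named character vector mapping short keys to canonical URIs.
#' @export
#' @examples
#' code_systems()[["snomed"]]
code_systems <- function() {
  c(
    snomed     = "http://snomed.info/sct",
    loinc      = "http://loinc.org",
    ucum       = "http://unitsofmeasure.org",
    eucast     = "https://example.org/fhir/microbiology/CodeSystem/eucast-susceptibility",
    hl7_interp = "http://terminology.hl7.org/CodeSystem/v3-ObservationInterpretation",
    local      = "https://example.org/fhir/microbiology/CodeSystem/local-components",
    ncbi       = "https://www.ncbi.nlm.nih.gov/gene",
    ebi        = "https://www.ebi.ac.uk/ena"
  )
}

resolve_system <- function(system) {
  sys <- code_systems()
  if (system %in% names(sys)) return(unname(sys[[system]]))
  system
}

#' Create a concept reference
#'
#' A `(system, code, display)` triple is the atom of every terminology binding
#' in the package. `system` may be a short key from [code_systems()] or a full
#' URI (fixture URIs are accepted as-is).
#'
#' @param system Code-system key or canonical URI.
#' @param code Code string; must be non-empty and contain no whitespace.
#' @param display Optional human-readable display string.
#' @return Object of class `mf_concept`.
#' @export
#' @examples
#' concept_ref("snomed", "260373001", "Detected (qualifier value)")
concept_ref <- function(system, code, display = NULL) {
  stopifnot(is.character(system), length(system) == 1L)
  system <- resolve_system(system)
  if (!is.character(code) || length(code) != 1L || !nzchar(code) ||
      grepl("\\s", code)) {
    stop("concept code must be a non-empty string without whitespace",
         call. = FALSE)
  }
  structure(
    list(system = system, code = code,
         display = if (!is.null(display)) as.character(display)),
    class = "mf_concept"
  )
}

#' @export
print.mf_concept <- function(x, ...) {
  cat(sprintf("<%s|%s>%s\n", x$system, x$code,
              if (is.null(x$display)) "" else paste0(" ", x$display)))
  invisible(x)
}

#' Test for a concept reference
#' @param x Object to test.
#' @return Logical scalar.
#' @export
is_concept_ref <- function(x) inherits(x, "mf_concept")

same_concept <- function(a, b) {
  is_concept_ref(a) && is_concept_ref(b) &&
    identical(a$system, b$system) && identical(a$code, b$code)
}

#' Registered UCUM units
#'
#' The UCUM subset accepted for numeric microbiology results. MIC/MLC values
#' use ug/mL, mg/L or [arb'U]/mL; the four colony-count codes each imply a
#' unit class (per volume, dimensionless count, per mass, CFU per volume);
#' "1" covers dimensionless values (cycle thresholds, scores) and
#' "{copies}/mL" viral loads. The micro sign is carried in its UCUM
#' case-sensitive ASCII form ("ug/mL").
#'
#' @param context Optional unit-class name: one of `"mic"`, `"count"`,
#'   or a colony-count LOINC code to get that code's unit.
#' @return Character vector of UCUM codes.
#' @export
ucum_units <- function(context = NULL) {
  classes <- list(
    mic = c("ug/mL", "mg/L", "[arb'U]/mL"),
    count = c("/mL", "1", "/g", "[CFU]/mL"),
    `49223-1` = "/mL", `564-5` = "1", `38436-2` = "/g", `20774-6` = "[CFU]/mL",
    other = c("1", "[arb'U]/mL", "{copies}/mL")
  )
  if (is.null(context)) return(unique(unlist(classes, use.names = FALSE)))
  if (!context %in% names(classes)) {
    stop("unknown unit context: ", context, call. = FALSE)
  }
  classes[[context]]
}

#' Create a quantity
#'
#' @param value Numeric scalar.
#' @param unit UCUM code from the registered subset ([ucum_units()]).
#' @return Object of class `mf_quantity`.
#' @export
#' @examples
#' quantity(0.25, "ug/mL")
quantity <- function(value, unit) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value)) {
    stop("quantity value must be a single number", call. = FALSE)
  }
  if (!is.character(unit) || length(unit) != 1L || !unit %in% ucum_units()) {
    stop("unit '", unit, "' is not in the registered UCUM subset",
         call. = FALSE)
  }
  structure(list(value = as.numeric(value), unit = unit),
            class = "mf_quantity")
}

#' @export
print.mf_quantity <- function(x, ...) {
  cat(sprintf("%g %s\n", x$value, x$unit))
  invisible(x)
}

is_quantity <- function(x) inherits(x, "mf_quantity")
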