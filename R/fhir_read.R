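# --- parsing helpers -------------------------------------------------------

cc_concept <- function(cc, which = 1L) {
  coding <- cc$coding[[which]]
  concept_ref(coding$system, coding$code, coding$display)
}

cc_codes <- function(cc) vapply(cc$coding, `[[`, character(1), "code")

quantity_from_json <- function(q) {
  quantity(as.numeric(q$value), q$code %||% q$unit)
}

component_code <- function(comp) comp$code$coding[[1]]$code

strip_obs_ref <- function(ref) sub("^Observation/", "", ref)

as_envelope <- function(x) {
  if (inherits(x, "mf_envelope")) return(x)
  profile <- unlist(x$meta$profile)[1] %||% NA_character_
  structure(list(resource_type = x$resourceType, profile_url = profile,
                 body = x),
            class = "mf_envelope")
}

dispatch_kind <- function(body) {
  reg <- observation_kinds()
  profiles <- vapply(reg$kind, profile_url, character(1))
  for (p in unlist(body$meta$profile)) {
    hit <- match(p, profiles)
    if (!is.na(hit)) return(reg$kind[hit])
  }
  # fall back on Observation.code fixed values and known code sets
  codes <- tryCatch(cc_codes(body$code), error = function(e) character(0))
  fixed <- c(`11475-1` = "culture", `117259009` = "microscopy",
             `92253-4` = "molecular", `1285113001` = "mdro_type",
             `99780-9` = "mrgn")
  for (code in codes) {
    if (code %in% names(fixed)) return(unname(fixed[[code]]))
    if (code %in% c("49223-1", "564-5", "38436-2", "20774-6")) {
      return("colony_count")
    }
    if (code %in% c(GENERIC_GENE_CODES, "72421-1")) {
      return("resistance_mechanism")
    }
    if (code == SEROLOGY_PROC_CODE) return("serology")
  }
  stop("cannot dispatch resource to an observation kind (profile ",
       "unrecognized and code carries no fixed value)", call. = FALSE)
}

# --- reader ----------------------------------------------------------------

#' Parse FHIR R4 JSON back into domain objects
#'
#' Inverse of [to_fhir()]: dispatches on `meta.profile` (falling back on the
#' fixed `Observation.code` values) and rebuilds the typed observation through
#' its constructor, so every model invariant is re-checked;
#' `from_fhir(to_fhir(x))` is the identity on valid objects. DiagnosticReport
#' resources are rebuilt as [microbiology_report()] objects. A resource of
#' any other type is a dispatch error.
#'
#' @param x An `mf_envelope` or a parsed resource tree (named list).
#' @param snapshots,catalog Terminology context for the re-validation.
#' @return An `mf_observation` or `mf_report`.
#' @export
from_fhir <- function(x, snapshots = cached_snapshots(),
                      catalog = default_catalog()) {
  env <- as_envelope(x)
  body <- env$body
  if (identical(body$resourceType, "DiagnosticReport")) {
    return(parse_report(body))
  }
  if (!identical(body$resourceType, "Observation")) {
    stop("cannot dispatch resourceType ", body$resourceType %||% "<missing>",
         call. = FALSE)
  }
  kind <- dispatch_kind(body)
  payload <- switch(kind,
    culture = parse_culture(body),
    colony_count = parse_colony(body),
    susceptibility = parse_susceptibility(body),
    microscopy = parse_microscopy(body),
    molecular = parse_molecular(body),
    serology = parse_serology(body),
    mdro_type = list(value = cc_concept(body$valueCodeableConcept)),
    mrgn = list(value = cc_concept(body$valueCodeableConcept)),
    resistance_mechanism = parse_resistance(body),
    virulence = list(test = cc_concept(body$code),
                     result = cc_concept(body$valueCodeableConcept))
  )
  payload$id <- body$id
  payload$specimen <- body$specimen$reference %||% NULL
  new_observation(kind, payload, snapshots, catalog)
}

components_with_code <- function(body, code) {
  Filter(function(comp) identical(component_code(comp), code),
         body$component %||% list())
}

parse_organisms <- function(body) {
  comps <- components_with_code(body, "410607006")
  orgs <- lapply(comps, function(comp) cc_concept(comp$valueCodeableConcept))
  if (length(orgs)) orgs else NULL
}

parse_culture <- function(body) {
  list(result = cc_concept(body$valueCodeableConcept),
       organism = parse_organisms(body),
       children = vapply(body$hasMember %||% list(), function(m) {
         strip_obs_ref(m$reference)
       }, character(1)))
}

parse_colony <- function(body) {
  out <- list(code = cc_concept(body$code))
  if (!is.null(body$valueQuantity)) {
    out$quantity <- quantity_from_json(body$valueQuantity)
  } else {
    out$semiquant <- cc_concept(body$valueCodeableConcept)
  }
  out
}

parse_susceptibility <- function(body) {
  out <- list(agent = cc_concept(body$code))
  if (!is.null(body$valueQuantity)) {
    out$mic <- quantity_from_json(body$valueQuantity)
  }
  interp <- body$interpretation
  if (!is.null(interp) && length(interp)) {
    coding <- interp[[1]]$coding[[1]]
    out$interpretation <- coding$code
    out$scheme <- if (identical(coding$system, resolve_system("eucast"))) {
      "EUCAST"
    } else if (identical(coding$system, resolve_system("hl7_interp"))) {
      "CLSI"
    }
    out$scheme_version <- coding$version %||% ""
  }
  if (!is.null(body$method)) out$method <- cc_concept(body$method)
  out
}

parse_microscopy <- function(body) {
  out <- list(result = cc_concept(body$valueCodeableConcept),
              method = cc_concept(body$method),
              organism = parse_organisms(body))
  for (comp in body$component %||% list()) {
    code <- component_code(comp)
    if (code %in% SCORE_CODES) {
      out$score <- list(code = cc_concept(comp$code),
                        value = as.integer(comp$valueQuantity$value))
    } else if (code == LOCAL_COMPONENTS$microscopy_quantity[1]) {
      if (!is.null(comp$valueQuantity)) {
        out$quantity <- quantity_from_json(comp$valueQuantity)
      } else {
        out$semiquant <- cc_concept(comp$valueCodeableConcept)
      }
    }
  }
  if (!is.null(body$note)) out$morphology <- body$note[[1]]$text
  out
}

parse_molecular <- function(body) {
  assay <- list()
  for (comp in body$component %||% list()) {
    code <- component_code(comp)
    if (code %in% ASSAY_CODES) {
      assay <- c(assay, list(list(code = cc_concept(comp$code),
                                  value = quantity_from_json(comp$valueQuantity))))
    }
  }
  list(result = cc_concept(body$valueCodeableConcept),
       organism = parse_organisms(body), assay = assay)
}

parse_serology <- function(body) {
  out <- list(test = cc_concept(body$code),
              result = cc_concept(body$valueCodeableConcept))
  for (comp in body$component %||% list()) {
    code <- component_code(comp)
    if (code == LOCAL_COMPONENTS$antigen[1]) {
      out$antigen_quantity <- quantity_from_json(comp$valueQuantity)
    } else if (code == LOCAL_COMPONENTS$antibody[1]) {
      out$antibody_quantity <- quantity_from_json(comp$valueQuantity)
    } else if (code == "77559007") {
      out$avidity <- list(value = if (!is.null(comp$valueQuantity)) {
        quantity_from_json(comp$valueQuantity)
      } else {
        cc_concept(comp$valueCodeableConcept)
      })
    }
  }
  out
}

parse_resistance <- function(body) {
  out <- list(test = cc_concept(body$code),
              result = cc_concept(body$valueCodeableConcept))
  comps <- components_with_code(body, LOCAL_COMPONENTS$gene[1])
  if (length(comps)) {
    coding <- comps[[1]]$valueCodeableConcept$coding[[1]]
    out$gene <- list(
      name = coding$display,
      source = if (identical(coding$system, resolve_system("ncbi"))) "NCBI"
               else "EMBL-EBI",
      identifier = coding$code
    )
  }
  out
}

parse_report <- function(body) {
  loinc_codes <- character(0)
  for (cc in body$category %||% list()) {
    for (coding in cc$coding) {
      if (identical(coding$system, resolve_system("loinc"))) {
        loinc_codes <- c(loinc_codes, coding$code)
      }
    }
  }
  study <- intersect(loinc_codes, STUDY_TYPES)[1]
  if (is.na(study)) {
    stop_invariant("category", "report-study-type",
                   "report category carries no microbiology study type")
  }
  microbiology_report(
    id = body$id,
    category = study,
    results = vapply(body$result %||% list(), function(r) {
      strip_obs_ref(r$reference)
    }, character(1)),
    conclusion = body$conclusion %||% NULL
  )
}

#' Lenient parse with issue reporting
#'
#' Like [from_fhir()] but never raises on content errors: profile violations
#' are returned as the validator's issue list and the object slot is `NULL`
#' when construction fails.
#'
#' @inheritParams from_fhir
#' @return List with elements `object` (observation/report or `NULL`) and
#'   `issues` (a [validate_resource()] data frame).
#' @export
parse_with_issues <- function(x, snapshots = cached_snapshots(),
                              catalog = default_catalog()) {
  env <- as_envelope(x)
  object <- tryCatch(from_fhir(env, snapshots, catalog),
                     error = function(e) NULL)
  list(object = object,
       issues = validate_resource(env, snapshots, catalog))
}
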