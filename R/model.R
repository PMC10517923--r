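# Fixed concept bindings used across the model.
CATEGORY_MICRO <- function() {
  concept_ref("loinc", "18725-2", "Microbiology studies (set)")
}

DETECTION_CODES <- c(detected = "260373001", `not-detected` = "260415000",
                     inconclusive = "419984006")
POSITIVITY_CODES <- c(positive = "10828004", `weakly-positive` = "260408008",
                      negative = "260385009", inconclusive = "419984006")
SCORE_CODES <- c("75371-5", "43391-2")
ASSAY_CODES <- c("398545005", "9718006")
AVIDITY_VALUE_CODES <- c(high = "75540009", low = "62482003")
GENERIC_GENE_CODES <- c("92251-8", "92246-8")
STUDY_TYPES <- c(bacterial = "92894-5", viral = "92893-7",
                 mycobacteriology = "96397-5", mycology = "96398-3",
                 parasitic = "92892-9")
MRGN_ANSWERS <- c(`2MRGN` = "LA33214-0", `3MRGN` = "LA33215-7",
                  `4MRGN` = "LA33216-5")
SEROLOGY_PROC_CODE <- "25231800"  # carried verbatim from the source model

#' Detection-style result concept
#'
#' The three-valued result used by culture, microscopy and virulence-factor
#' observations: a test either detected the target, did not, or was
#' inconclusive.
#'
#' @param value One of `"detected"`, `"not-detected"`, `"inconclusive"`.
#' @return An [concept_ref()] for the corresponding SNOMED CT qualifier.
#' @export
#' @examples
#' detection_concept("detected")
detection_concept <- function(value = c("detected", "not-detected",
                                        "inconclusive")) {
  value <- match.arg(value)
  displays <- c(detected = "Detected (qualifier value)",
                `not-detected` = "Not detected (qualifier value)",
                inconclusive = "Inconclusive (qualifier value)")
  concept_ref("snomed", DETECTION_CODES[[value]], displays[[value]])
}

#' Positivity-style result concept
#'
#' The four-valued result used by molecular, serology/immunology and
#' resistance-mechanism observations.
#'
#' @param value One of `"positive"`, `"weakly-positive"`, `"negative"`,
#'   `"inconclusive"`.
#' @return An [concept_ref()] for the corresponding SNOMED CT qualifier.
#' @export
positivity_concept <- function(value = c("positive", "weakly-positive",
                                         "negative", "inconclusive")) {
  value <- match.arg(value)
  displays <- c(positive = "Positive (qualifier value)",
                `weakly-positive` = "Weakly positive (qualifier value)",
                negative = "Negative (qualifier value)",
                inconclusive = "Inconclusive (qualifier value)")
  concept_ref("snomed", POSITIVITY_CODES[[value]], displays[[value]])
}

#' Observation-kind registry
#'
#' The ten observation kinds the model covers, each assigned to one of the
#' three main diagnostic blocks (culture, molecular, serology) or to the
#' further-properties group, together with its result style (`detection` =
#' 3-valued detected set, `positivity` = 4-valued positive set, `NA` = no
#' coded primary result or a kind-specific one) and its profile name.
#'
#' @return `data.frame` with columns `kind`, `block`, `result_style`,
#'   `profile`.
#' @export
#' @examples
#' table(observation_kinds()$block)
observation_kinds <- function() {
  data.frame(
    kind = c("culture", "colony_count", "susceptibility", "microscopy",
             "molecular", "serology", "mdro_type", "mrgn",
             "resistance_mechanism", "virulence"),
    block = c("culture", "culture", "culture", "culture",
              "molecular", "serology", "further-properties",
              "further-properties", "further-properties",
              "further-properties"),
    result_style = c("detection", NA, NA, "detection",
                     "positivity", "positivity", NA, NA,
                     "positivity", "detection"),
    profile = c("culture-detection", "colony-count", "susceptibility-test",
                "microscopy", "molecular-detection", "serology-immunology",
                "mdro-type", "mrgn-classification", "resistance-mechanism",
                "virulence-factor"),
    stringsAsFactors = FALSE
  )
}

#' Diagnostic blocks of the model
#'
#' @return Character vector: the three main diagnostic blocks plus the
#'   further-properties group, in canonical order.
#' @export
model_blocks <- function() {
  c("culture", "molecular", "serology", "further-properties")
}

profile_url <- function(kind) {
  reg <- observation_kinds()
  profile <- reg$profile[match(kind, reg$kind)]
  paste0("https://example.org/fhir/microbiology/StructureDefinition/", profile)
}

REPORT_PROFILE_URL <-
  "https://example.org/fhir/microbiology/StructureDefinition/microbiology-report"

stop_invariant <- function(field, rule, msg) {
  stop(structure(
    class = c("mf_invariant_error", "error", "condition"),
    list(message = sprintf("[%s] %s: %s", rule, field, msg), call = NULL,
         field = field, rule_id = rule)
  ))
}

need_concept <- function(x, field, rule = "type") {
  if (!is_concept_ref(x)) stop_invariant(field, rule, "must be a concept_ref")
  x
}

need_result <- function(x, style, field = "result") {
  need_concept(x, field)
  codes <- if (style == "detection") DETECTION_CODES else POSITIVITY_CODES
  if (!identical(x$system, resolve_system("snomed")) || !x$code %in% codes) {
    stop_invariant(field, "result-vs-mismatch",
                   sprintf("code %s is not in the %s result value set",
                           x$code, style))
  }
  x
}

is_detected <- function(result) {
  identical(result$code, DETECTION_CODES[["detected"]])
}

as_organism_list <- function(organism, snapshots, catalog, field = "organism") {
  if (is.null(organism)) return(list())
  if (is_concept_ref(organism)) organism <- list(organism)
  vs <- catalog_vs(catalog, "organism")
  for (o in organism) {
    need_concept(o, field)
    if (!valueset_contains(vs, o, snapshots)) {
      stop_invariant(field, "organism-vs",
                     sprintf("code %s is outside the organism value set", o$code))
    }
  }
  organism
}

#' Construct a microbiology observation
#'
#' Builds a typed observation of one of the ten registered kinds, enforcing
#' every structural invariant of the model: fixed codes, result value-set
#' membership, choice-type exclusivity, mandatory susceptibility version, the
#' organism-implies-detected rule, and the restricted component codes.
#' Violations raise an `mf_invariant_error` naming the offending field and the
#' rule id. Every observation implicitly carries the fixed microbiology
#' category (LOINC 18725-2); serialization adds it.
#'
#' Kind-specific payload fields (all observations also take `id` and an
#' optional `specimen` reference string):
#' \describe{
#'   \item{culture}{`result` (detection concept), optional `organism`
#'     (concept or list of concepts in the organism value set; requires
#'     `result` detected), optional `children` (character ids of linked
#'     colony-count / susceptibility observations).}
#'   \item{colony_count}{`code` (one of the four colony-count LOINC codes),
#'     exactly one of `quantity` ([quantity()], unit matching the code) or
#'     `semiquant` (semiquantitative concept).}
#'   \item{susceptibility}{`agent` (LOINC susceptibility-test concept),
#'     optional `mic` (quantity in ug/mL, mg/L or \[arb'U\]/mL), optional
#'     `interpretation` (category string), `scheme` (`"EUCAST"` or `"CLSI"`),
#'     `scheme_version` (non-empty whenever an interpretation is present),
#'     optional `method` concept.}
#'   \item{microscopy}{`result`, `method` (enumerated procedure or a staining
#'     method), optional `organism`, `morphology` (free text), `score`
#'     (`list(code, value)` with code 75371-5 or 43391-2), `quantity` or
#'     `semiquant`.}
#'   \item{molecular}{`result` (positivity concept), optional `organism`,
#'     optional `assay` — list of `list(code, value)` where code is the
#'     nucleic-acid-assay or PCR procedure and value a [quantity()] (cycle
#'     threshold, viral load).}
#'   \item{serology}{`test` (the fixed immunology procedure or a serology
#'     LOINC code), `result`, optional `antigen_quantity`,
#'     `antibody_quantity`, `avidity` (`list(value)`, value a high/low
#'     concept or a quantity).}
#'   \item{mdro_type}{`value` — concept under one of the three
#'     antimicrobial-resistant organism hierarchies.}
#'   \item{mrgn}{`value` — one of the three MRGN LOINC answer codes.}
#'   \item{resistance_mechanism}{`test` (resistance gene/mutation code or a
#'     generic gene-detected code), `result`, `gene`
#'     (`list(name, source, identifier)`, source `"NCBI"` or `"EMBL-EBI"`;
#'     mandatory with the generic codes).}
#'   \item{virulence}{`test` (virulence-factor LOINC code), `result`
#'     (detection concept).}
#' }
#'
#' @param kind One of `observation_kinds()$kind`.
#' @param payload Named list of fields as described above.
#' @param snapshots,catalog Terminology context used for value-set checks.
#' @param validate When `FALSE` (untrusted input, e.g. raw LIS rows) an
#'   invariant violation does not raise: the observation is built as-is so it
#'   can be serialized and flagged by [validate_resource()] downstream.
#' @return Object of classes `mf_obs_<kind>` and `mf_observation`.
#' @export
#' @examples
#' obs <- new_observation("culture", list(
#'   id = "cx1", result = detection_concept("detected"),
#'   organism = concept_ref("snomed", "112283007", "Escherichia coli (organism)")))
#' obs$result$code
new_observation <- function(kind, payload,
                            snapshots = cached_snapshots(),
                            catalog = default_catalog(),
                            validate = TRUE) {
  reg <- observation_kinds()
  if (!kind %in% reg$kind) stop("unknown observation kind: ", kind, call. = FALSE)
  if (is.null(payload$id) || !nzchar(payload$id)) {
    stop_invariant("id", "id-required", "caller must supply an id")
  }
  if (!validate) {
    validated <- tryCatch(
      new_observation(kind, payload, snapshots, catalog, validate = TRUE),
      mf_invariant_error = function(e) NULL)
    if (!is.null(validated)) return(validated)
    return(unchecked_observation(kind, payload))
  }
  obs <- list(kind = kind, id = as.character(payload$id),
              specimen = payload$specimen %||% NULL)
  obs <- c(obs, switch(kind,
    culture = build_culture(payload, snapshots, catalog),
    colony_count = build_colony(payload, catalog),
    susceptibility = build_susceptibility(payload, snapshots, catalog),
    microscopy = build_microscopy(payload, snapshots, catalog),
    molecular = build_molecular(payload, snapshots, catalog),
    serology = build_serology(payload, catalog),
    mdro_type = build_mdro(payload, snapshots, catalog),
    mrgn = build_mrgn(payload),
    resistance_mechanism = build_resistance(payload, snapshots, catalog),
    virulence = build_virulence(payload, snapshots, catalog)
  ))
  structure(obs, class = c(paste0("mf_obs_", kind), "mf_observation"))
}

# Shape a payload into an observation without invariant checks (lenient
# ingest path); field normalization mirrors the validated builders.
unchecked_observation <- function(kind, payload) {
  obs <- list(kind = kind, id = as.character(payload$id),
              specimen = payload$specimen %||% NULL)
  rest <- payload[setdiff(names(payload), c("id", "specimen"))]
  if (!is.null(rest$organism) && is_concept_ref(rest$organism)) {
    rest$organism <- list(rest$organism)
  }
  if (kind %in% c("culture", "microscopy", "molecular") &&
      is.null(rest$organism)) {
    rest$organism <- list()
  }
  if (kind == "culture") {
    rest$children <- unique(as.character(rest$children %||% character(0)))
  }
  if (kind == "molecular" && is.null(rest$assay)) rest$assay <- list()
  structure(c(obs, rest),
            class = c(paste0("mf_obs_", kind), "mf_observation"))
}

build_culture <- function(p, snapshots, catalog) {
  result <- need_result(p$result, "detection")
  organism <- as_organism_list(p$organism, snapshots, catalog)
  if (length(organism) && !is_detected(result)) {
    stop_invariant("organism", "organism-requires-detected",
                   "an organism may only accompany a detected result")
  }
  list(result = result, organism = organism,
       children = unique(as.character(p$children %||% character(0))))
}

build_colony <- function(p, catalog) {
  code <- need_concept(p$code, "code")
  vs <- catalog_vs(catalog, "colony-count-codes")
  if (!any(vapply(vs$members, same_concept, logical(1), code))) {
    stop_invariant("code", "colony-code-vs",
                   sprintf("%s is not a colony-count code", code$code))
  }
  has_q <- !is.null(p$quantity)
  has_s <- !is.null(p$semiquant)
  if (has_q == has_s) {
    stop_invariant("value", "colony-choice-exclusive",
                   "exactly one of quantity/semiquant must be given")
  }
  if (has_q) {
    if (!is_quantity(p$quantity)) stop_invariant("quantity", "type", "not a quantity")
    want <- ucum_units(code$code)
    if (!p$quantity$unit %in% want) {
      stop_invariant("quantity.unit", "ucum-unit",
                     sprintf("unit %s does not match code %s (expected %s)",
                             p$quantity$unit, code$code, want))
    }
  } else {
    need_concept(p$semiquant, "semiquant")
    vs2 <- catalog_vs(catalog, "semiquantitative-result")
    if (!any(vapply(vs2$members, same_concept, logical(1), p$semiquant))) {
      stop_invariant("semiquant", "result-vs-mismatch",
                     "not a semiquantitative result concept")
    }
  }
  list(code = code, quantity = p$quantity %||% NULL,
       semiquant = p$semiquant %||% NULL)
}

SCHEME_SETS <- list(EUCAST = c("S", "I", "R"),
                    CLSI = c("S", "SDD", "I", "R", "NS"))

build_susceptibility <- function(p, snapshots, catalog) {
  agent <- need_concept(p$agent, "agent")
  vs <- catalog_vs(catalog, "susceptibility-tests")
  if (!valueset_contains(vs, agent, snapshots)) {
    stop_invariant("agent", "susc-code-vs",
                   sprintf("%s is not a phenotypic susceptibility test", agent$code))
  }
  if (!is.null(p$mic)) {
    if (!is_quantity(p$mic)) stop_invariant("mic", "type", "not a quantity")
    if (!p$mic$unit %in% ucum_units("mic")) {
      stop_invariant("mic.unit", "ucum-unit",
                     sprintf("%s is not a MIC/MLC unit", p$mic$unit))
    }
  }
  interp <- p$interpretation %||% NULL
  scheme <- p$scheme %||% NULL
  version <- p$scheme_version %||% ""
  if (!is.null(interp)) {
    if (is.null(scheme) || !scheme %in% names(SCHEME_SETS)) {
      stop_invariant("scheme", "susc-interpretation-vs",
                     "scheme must be EUCAST or CLSI when an interpretation is present")
    }
    if (!interp %in% SCHEME_SETS[[scheme]]) {
      stop_invariant("interpretation", "susc-interpretation-vs",
                     sprintf("%s is not a %s category", interp, scheme))
    }
    if (!nzchar(version)) {
      stop_invariant("scheme_version", "susc-version-required",
                     "the standard's version is mandatory with an interpretation")
    }
  }
  if (!is.null(p$method)) need_concept(p$method, "method")
  # scheme/version only carry meaning alongside an interpretation; dropping
  # them otherwise keeps serialization lossless
  list(agent = agent, mic = p$mic %||% NULL, interpretation = interp,
       scheme = if (!is.null(interp)) scheme,
       scheme_version = if (!is.null(interp)) version,
       method = p$method %||% NULL)
}

build_microscopy <- function(p, snapshots, catalog) {
  result <- need_result(p$result, "detection")
  method <- need_concept(p$method, "method")
  in_enum <- any(vapply(catalog_vs(catalog, "microscopy-methods")$members,
                        same_concept, logical(1), method))
  in_stain <- !in_enum &&
    valueset_contains(catalog_vs(catalog, "staining-methods"), method, snapshots)
  if (!in_enum && !in_stain) {
    stop_invariant("method", "method-vs",
                   sprintf("%s is not a registered microscopy method", method$code))
  }
  organism <- as_organism_list(p$organism, snapshots, catalog)
  score <- p$score %||% NULL
  if (!is.null(score)) {
    need_concept(score$code, "score.code")
    if (!score$code$code %in% SCORE_CODES) {
      stop_invariant("score.code", "score-code-fixed",
                     "score code must be the Bartlett or vaginosis score")
    }
    score$value <- as.integer(score$value)
  }
  has_q <- !is.null(p$quantity)
  has_s <- !is.null(p$semiquant)
  if (has_q && has_s) {
    stop_invariant("value", "colony-choice-exclusive",
                   "quantity and semiquant are alternatives")
  }
  if (has_q && !is_quantity(p$quantity)) {
    stop_invariant("quantity", "type", "not a quantity")
  }
  if (has_s) {
    vs2 <- catalog_vs(catalog, "semiquantitative-result")
    if (!any(vapply(vs2$members, same_concept, logical(1), p$semiquant))) {
      stop_invariant("semiquant", "result-vs-mismatch",
                     "not a semiquantitative result concept")
    }
  }
  list(result = result, method = method, organism = organism,
       morphology = p$morphology %||% NULL, score = score,
       quantity = p$quantity %||% NULL, semiquant = p$semiquant %||% NULL)
}

build_molecular <- function(p, snapshots, catalog) {
  result <- need_result(p$result, "positivity")
  organism <- as_organism_list(p$organism, snapshots, catalog)
  assay <- p$assay %||% list()
  for (a in assay) {
    need_concept(a$code, "assay.code")
    if (!a$code$code %in% ASSAY_CODES) {
      stop_invariant("assay.code", "assay-component-code",
                     "assay component must be nucleic-acid assay or PCR")
    }
    if (!is_quantity(a$value)) {
      stop_invariant("assay.value", "type", "assay value must be a quantity")
    }
  }
  list(result = result, organism = organism, assay = assay)
}

build_serology <- function(p, catalog) {
  test <- need_concept(p$test, "test")
  snomed_proc <- identical(test$system, resolve_system("snomed")) &&
    identical(test$code, SEROLOGY_PROC_CODE)
  in_vs <- any(vapply(catalog_vs(catalog, "serology-tests")$members,
                      same_concept, logical(1), test))
  if (!snomed_proc && !in_vs) {
    stop_invariant("test", "serology-code-vs",
                   "test must be the immunology procedure or a serology LOINC code")
  }
  result <- need_result(p$result, "positivity")
  for (f in c("antigen_quantity", "antibody_quantity")) {
    if (!is.null(p[[f]]) && !is_quantity(p[[f]])) {
      stop_invariant(f, "type", "must be a quantity")
    }
  }
  avidity <- p$avidity %||% NULL
  if (!is.null(avidity)) {
    v <- avidity$value
    if (is_concept_ref(v)) {
      if (!v$code %in% AVIDITY_VALUE_CODES) {
        stop_invariant("avidity.value", "avidity-value-vs",
                       "qualitative avidity must be high or low")
      }
    } else if (!is_quantity(v)) {
      stop_invariant("avidity.value", "type", "must be a concept or quantity")
    }
  }
  list(test = test, result = result,
       antigen_quantity = p$antigen_quantity %||% NULL,
       antibody_quantity = p$antibody_quantity %||% NULL,
       avidity = avidity)
}

build_mdro <- function(p, snapshots, catalog) {
  value <- need_concept(p$value, "value")
  if (!valueset_contains(catalog_vs(catalog, "mdro-type"), value, snapshots)) {
    stop_invariant("value", "mdro-value-vs",
                   "value must lie under a resistant-organism hierarchy")
  }
  list(value = value)
}

build_mrgn <- function(p) {
  value <- need_concept(p$value, "value")
  if (!value$code %in% MRGN_ANSWERS) {
    stop_invariant("value", "mrgn-value-vs",
                   "value must be one of the three MRGN answer codes")
  }
  list(value = value)
}

build_resistance <- function(p, snapshots, catalog) {
  test <- need_concept(p$test, "test")
  generic <- test$code %in% GENERIC_GENE_CODES
  ok <- generic ||
    any(vapply(catalog_vs(catalog, "resistance-genes")$members,
               same_concept, logical(1), test)) ||
    valueset_contains(catalog_vs(catalog, "resistance-mutations"), test,
                      snapshots)
  if (!ok) {
    stop_invariant("test", "resistance-code-vs",
                   sprintf("%s is not a resistance gene/mutation test", test$code))
  }
  result <- need_result(p$result, "positivity")
  gene <- p$gene %||% NULL
  if (generic && is.null(gene)) {
    stop_invariant("gene", "gene-component-required",
                   "generic gene-detected codes require a named gene")
  }
  if (!is.null(gene)) {
    if (is.null(gene$name) || !nzchar(gene$name) ||
        is.null(gene$source) || !gene$source %in% c("NCBI", "EMBL-EBI") ||
        is.null(gene$identifier) || !nzchar(gene$identifier)) {
      stop_invariant("gene", "gene-component-required",
                     "gene needs name, source (NCBI/EMBL-EBI) and identifier")
    }
    gene <- list(name = gene$name, source = gene$source,
                 identifier = gene$identifier)
  }
  list(test = test, result = result, gene = gene)
}

build_virulence <- function(p, snapshots, catalog) {
  test <- need_concept(p$test, "test")
  if (!any(vapply(catalog_vs(catalog, "virulence-tests")$members,
                  same_concept, logical(1), test))) {
    stop_invariant("test", "virulence-code-vs",
                   sprintf("%s is not a virulence-factor test", test$code))
  }
  list(test = test, result = need_result(p$result, "detection"))
}

#' @export
print.mf_observation <- function(x, ...) {
  cat(sprintf("<microbiology observation %s [%s]>\n", x$id, x$kind))
  invisible(x)
}

#' Link child observations to a culture
#'
#' Cultures that detected an organism can reference the observations that
#' further characterize it (colony counts, susceptibility tests) — the
#' has-member relation of the serialized form. Linking to a culture whose
#' result is not "detected" is an invariant violation; duplicates are
#' dropped, order of first appearance is preserved.
#'
#' @param culture A culture observation.
#' @param children Character vector of observation ids.
#' @return The culture with updated `children`.
#' @export
link_culture_children <- function(culture, children) {
  stopifnot(inherits(culture, "mf_obs_culture"))
  if (!is_detected(culture$result)) {
    stop_invariant("children", "hasmember-requires-detected",
                   "only a detected culture can have member observations")
  }
  culture$children <- unique(c(culture$children, as.character(children)))
  culture
}

#' Construct a microbiology diagnostic report
#'
#' @param id Report id.
#' @param category Study type: one of `"bacterial"`, `"viral"`,
#'   `"mycobacteriology"`, `"mycology"`, `"parasitic"` (or the corresponding
#'   LOINC code).
#' @param results Character vector of observation ids the report collects.
#' @param conclusion Optional free-text conclusion.
#' @return Object of class `mf_report`.
#' @export
microbiology_report <- function(id, category, results,
                                conclusion = NULL) {
  if (category %in% names(STUDY_TYPES)) category <- STUDY_TYPES[[category]]
  if (!category %in% STUDY_TYPES) {
    stop_invariant("category", "report-study-type",
                   "category must be one of the five microbiology study types")
  }
  structure(list(id = as.character(id), category = category,
                 results = as.character(results),
                 conclusion = conclusion %||% NULL),
            class = "mf_report")
}

#' @export
print.mf_report <- function(x, ...) {
  cat(sprintf("<microbiology report %s (%s): %d results>\n",
              x$id, x$category, length(x$results)))
  invisible(x)
}
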