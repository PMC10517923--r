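#' Antibiotic groups of the MRGN scheme
#'
#' The four antibiotic groups the KRINKO MRGN classification scores:
#' ureidopenicillins, 3rd/4th-generation cephalosporins, carbapenems and
#' fluoroquinolones.
#'
#' @return Character vector of the four group names.
#' @export
mrgn_groups <- function() {
  c("ureidopenicillins", "cephalosporins", "carbapenems", "fluoroquinolones")
}

#' Marker antibiotics per MRGN group
#'
#' Maps the susceptibility-test codes the synthetic generator (and the LIS
#' conversion) uses onto the four MRGN antibiotic groups.
#'
#' @return `data.frame` with columns `agent_code`, `agent`, `group`.
#' @export
mrgn_agent_groups <- function() {
  data.frame(
    agent_code = c("99001-1", "99002-2", "99003-3", "99005-5", "99004-4"),
    agent = c("Piperacillin", "Cefotaxime", "Meropenem", "Meropenem",
              "Ciprofloxacin"),
    group = c("ureidopenicillins", "cephalosporins", "carbapenems",
              "carbapenems", "fluoroquinolones"),
    stringsAsFactors = FALSE
  )
}

PSEUDOMONAS_AERUGINOSA <- "52499004"
GRAM_NEGATIVE_FIXTURE <- c("112283007", "56415008", "52499004", "990001001",
                           "990001005")

is_p_aeruginosa <- function(species, snapshot) {
  code <- if (is_concept_ref(species)) species$code else as.character(species)
  if (identical(code, PSEUDOMONAS_AERUGINOSA)) return(TRUE)
  if (!is.null(snapshot) && has_concept(snapshot, code)) {
    return(is_descendant(snapshot, code, PSEUDOMONAS_AERUGINOSA))
  }
  FALSE
}

#' Classify a Gram-negative isolate into MRGN categories
#'
#' Applies the KRINKO multiresistance rules to the susceptibility pattern of
#' a Gram-negative isolate over the four antibiotic groups ([mrgn_groups()]).
#' Rules fire in order: (1) a detected carbapenemase forces 4MRGN regardless
#' of the susceptibility results; (2) carbapenem resistance forces 4MRGN for
#' every species except *Pseudomonas aeruginosa*; (3) otherwise the number
#' `n` of groups tested resistant decides — `n = 4` gives 4MRGN, `n = 3`
#' 3MRGN, and `n = 2` gives 2MRGN only in the neonatology setting (outside
#' neonatology the 2MRGN label is not used and the isolate is not
#' categorized).
#'
#' By default only the category R counts as resistant: I ("intermediate /
#' susceptible - increased exposure") denotes attainable exposure, not
#' resistance. Set `count_intermediate = TRUE` to also count I, since local
#' practice varies. A group reported `"NT"` (not tested) counts as
#' not-resistant and attaches a warning, because under-testing can
#' under-classify.
#'
#' @param species Species as an [concept_ref()] or a bare SNOMED code string.
#' @param groups Named character vector or list over all four groups of
#'   [mrgn_groups()], values in `S`, `I`, `R`, `NT`.
#' @param carbapenemase Was a carbapenemase detected?
#' @param neonatology Neonatology setting (enables the 2MRGN label)?
#' @param snapshot Hierarchical snapshot used for the species checks
#'   (P. aeruginosa subtree, Gram-negative fixture set); defaults to the
#'   bundled fixture.
#' @param count_intermediate Count I as resistant for the n-of-4 rule?
#' @return Object of class `mf_mrgn_result`: list with `category`
#'   (`"2MRGN"`, `"3MRGN"`, `"4MRGN"` or `"none"`), `answer` (the LOINC
#'   answer [concept_ref()], `NULL` when uncategorized), `n_resistant`,
#'   `rationale` (ordered ids of the rules that fired) and `warnings`.
#' @export
#' @examples
#' mrgn_classify("112283007",
#'   c(ureidopenicillins = "R", cephalosporins = "R",
#'     carbapenems = "S", fluoroquinolones = "R"))$category
mrgn_classify <- function(species, groups, carbapenemase = FALSE,
                          neonatology = FALSE, snapshot = NULL,
                          count_intermediate = FALSE) {
  if (is.null(snapshot)) {
    snapshot <- cached_snapshots()[[resolve_system("snomed")]]
  }
  groups <- unlist(groups)
  missing_groups <- setdiff(mrgn_groups(), names(groups))
  if (length(missing_groups)) {
    stop("missing antibiotic group(s): ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  }
  groups <- groups[mrgn_groups()]
  bad <- !groups %in% c("S", "I", "R", "NT")
  if (any(bad)) {
    stop("group results must be S, I, R or NT; got ",
         paste(unique(groups[bad]), collapse = ", "), call. = FALSE)
  }
  warnings <- character(0)
  species_code <- if (is_concept_ref(species)) species$code else
    as.character(species)
  gram_negative <- species_code %in% GRAM_NEGATIVE_FIXTURE ||
    (has_concept(snapshot, species_code) &&
       any(GRAM_NEGATIVE_FIXTURE %in% c(species_code,
                                        ancestors(snapshot, species_code))))
  if (!gram_negative) {
    warnings <- c(warnings, paste0("species ", species_code,
      " is not in the Gram-negative fixture set; classification computed anyway"))
  }
  if (any(groups == "NT")) {
    warnings <- c(warnings,
      "one or more groups not tested; counted as not-resistant, the category may under-classify")
  }
  resistant <- groups == "R" | (count_intermediate & groups == "I")
  n <- sum(resistant)
  rationale <- character(0)
  category <- "none"
  if (isTRUE(carbapenemase)) {
    category <- "4MRGN"
    rationale <- "carbapenemase-4mrgn"
  } else if (resistant[["carbapenems"]] &&
             !is_p_aeruginosa(species, snapshot)) {
    category <- "4MRGN"
    rationale <- "carbapenem-resistant-4mrgn"
  } else if (n == 4L) {
    category <- "4MRGN"
    rationale <- "four-group-resistance"
  } else if (n == 3L) {
    category <- "3MRGN"
    rationale <- "three-group-resistance"
  } else if (n == 2L) {
    if (isTRUE(neonatology)) {
      category <- "2MRGN"
      rationale <- "two-group-neonatology"
    } else {
      rationale <- "two-group-non-neonatology"
    }
  } else {
    rationale <- "insufficient-resistance"
  }
  structure(
    list(category = category,
         answer = if (category != "none") {
           concept_ref("loinc", MRGN_ANSWERS[[category]], category)
         },
         n_resistant = n, rationale = rationale, warnings = warnings),
    class = "mf_mrgn_result"
  )
}

#' @export
print.mf_mrgn_result <- function(x, ...) {
  cat(sprintf("<MRGN %s (n resistant = %d; %s)>\n", x$category,
              x$n_resistant, paste(x$rationale, collapse = ", ")))
  invisible(x)
}

#' Encode an MRGN result as an observation
#'
#' @param result An `mf_mrgn_result` with a category (`"none"` cannot be
#'   encoded and raises an error).
#' @param id Observation id.
#' @param specimen Optional specimen reference.
#' @return An `mf_observation` of kind `mrgn` (code 99780-9, value the
#'   matching LOINC answer code).
#' @export
mrgn_to_observation <- function(result, id, specimen = NULL) {
  stopifnot(inherits(result, "mf_mrgn_result"))
  if (identical(result$category, "none")) {
    stop("an uncategorized isolate cannot be encoded as an MRGN observation",
         call. = FALSE)
  }
  new_observation("mrgn", list(id = id, specimen = specimen,
                               value = result$answer))
}

#' Classify a table of isolates
#'
#' Vectorized CSV-friendly wrapper over [mrgn_classify()]. Input columns:
#' `isolate_id`, `species_code`, one column per group of [mrgn_groups()]
#' (values S/I/R/NT), `carbapenemase` and `neonatology` (logical or
#' "true"/"false").
#'
#' @param df Input data frame.
#' @param snapshot Optional hierarchical snapshot (defaults to the bundled
#'   fixture).
#' @return The input with `category`, `answer_code` and `rationale` columns
#'   appended.
#' @export
classify_mrgn_table <- function(df, snapshot = NULL) {
  required <- c("isolate_id", "species_code", mrgn_groups(),
                "carbapenemase", "neonatology")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  as_flag <- function(x) tolower(as.character(x)) %in% c("true", "1", "t", "yes")
  out <- df
  res <- lapply(seq_len(nrow(df)), function(i) {
    mrgn_classify(as.character(df$species_code[i]),
                  vapply(mrgn_groups(), function(g) as.character(df[[g]][i]),
                         character(1)),
                  carbapenemase = as_flag(df$carbapenemase[i]),
                  neonatology = as_flag(df$neonatology[i]),
                  snapshot = snapshot)
  })
  out$category <- vapply(res, `[[`, character(1), "category")
  out$answer_code <- vapply(res, function(r) {
    if (is.null(r$answer)) NA_character_ else r$answer$code
  }, character(1))
  out$rationale <- vapply(res, function(r) {
    paste(r$rationale, collapse = ";")
  }, character(1))
  out
}
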