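#' Define a value set
#'
#' A value set is either *extensional* (an enumerated list of concept
#' references) or *intensional* (a rule evaluated against a terminology
#' snapshot). Exactly one of `members` / `rule` must be supplied, matching
#' `kind`.
#'
#' Intensional rules come in two dialects. Hierarchical rules (ECL subset)
#' carry `include` — a list of `list(op, code)` entries where `op` is `"<"`
#' (strict descendants) or `"<<"` (descendant-or-self) — and optionally
#' `exclude`, a character vector of roots whose descendant-or-self subtrees
#' are removed; exclusions dominate inclusions. Tabular rules (LOINC parts)
#' carry `constraints` — a list of `list(part, op, value)` with `part` one of
#' property/method/class/component and `op` one of `"equals"`, `"not-equals"`,
#' `"in"`; matching is case-insensitive exact string comparison and all
#' constraints are conjoined.
#'
#' @param url Canonical URL identifying the value set.
#' @param kind `"extensional"` or `"intensional"`.
#' @param members List of [concept_ref()] objects (extensional only).
#' @param rule List describing the rule (intensional only); must carry
#'   `dialect` (`"hierarchical"`/`"tabular"`), `system`, and the fields above.
#' @param name Optional short name for catalog lookup.
#' @return Object of class `mf_valueset`.
#' @export
valueset_def <- function(url, kind = c("extensional", "intensional"),
                         members = NULL, rule = NULL, name = NULL) {
  kind <- match.arg(kind)
  if (kind == "extensional") {
    if (is.null(members) || !is.null(rule)) {
      stop("extensional value set must have members and no rule", call. = FALSE)
    }
    stopifnot(all(vapply(members, is_concept_ref, logical(1))))
  } else {
    if (is.null(rule) || !is.null(members)) {
      stop("intensional value set must have a rule and no members",
           call. = FALSE)
    }
    if (!rule$dialect %in% c("hierarchical", "tabular")) {
      stop("rule dialect must be hierarchical or tabular", call. = FALSE)
    }
    rule$system <- resolve_system(rule$system)
    if (rule$dialect == "hierarchical" && !length(rule$include)) {
      stop("hierarchical rule needs at least one include root", call. = FALSE)
    }
    if (rule$dialect == "tabular" && !length(rule$constraints)) {
      stop("tabular rule needs at least one part constraint", call. = FALSE)
    }
  }
  structure(list(url = url, name = name, kind = kind,
                 members = members, rule = rule),
            class = "mf_valueset")
}

#' @export
print.mf_valueset <- function(x, ...) {
  cat(sprintf("<valueset %s (%s, %s)>\n",
              x$name %||% x$url, x$kind,
              if (x$kind == "extensional") {
                sprintf("%d members", length(x$members))
              } else x$rule$dialect))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

snapshot_for <- function(snapshots, system) {
  snap <- snapshots[[system]]
  if (is.null(snap)) {
    stop("no snapshot loaded for system ", system,
         " (configuration error)", call. = FALSE)
  }
  snap
}

#' Expand a value set
#'
#' Materializes the full membership of a value set. Extensional sets expand
#' to their members verbatim (duplicate-free); hierarchical intensional sets
#' to the union of the include subtrees minus the descendant-or-self closure
#' of every exclusion root; tabular intensional sets to the codes whose parts
#' satisfy every constraint.
#'
#' @param vs An `mf_valueset`.
#' @param snapshots Named list of snapshots keyed by system URI
#'   (see [default_snapshots()]).
#' @return `data.frame` with columns `system`, `code`, `display`, sorted by
#'   code; one row per member.
#' @export
expand_valueset <- function(vs, snapshots = default_snapshots()) {
  stopifnot(inherits(vs, "mf_valueset"))
  if (vs$kind == "extensional") {
    out <- data.frame(
      system = vapply(vs$members, `[[`, character(1), "system"),
      code = vapply(vs$members, `[[`, character(1), "code"),
      display = vapply(vs$members, function(m) m$display %||% NA_character_,
                       character(1)),
      stringsAsFactors = FALSE
    )
    out <- out[!duplicated(paste(out$system, out$code)), , drop = FALSE]
  } else if (vs$rule$dialect == "hierarchical") {
    snap <- snapshot_for(snapshots, vs$rule$system)
    codes <- character(0)
    for (inc in vs$rule$include) {
      if (!has_concept(snap, inc$code)) stop_unknown_concept(inc$code, snap$system)
      codes <- c(codes, descendants(snap, inc$code,
                                    include_self = identical(inc$op, "<<")))
    }
    codes <- unique(codes)
    for (exc in vs$rule$exclude %||% character(0)) {
      if (!has_concept(snap, exc)) stop_unknown_concept(exc, snap$system)
      codes <- setdiff(codes, descendants(snap, exc, include_self = TRUE))
    }
    out <- data.frame(system = rep(snap$system, length(codes)), code = codes,
                      display = display_of(snap, codes),
                      stringsAsFactors = FALSE)
  } else {
    snap <- snapshot_for(snapshots, vs$rule$system)
    if (snap$dialect != "tabular") {
      stop("tabular rule needs a tabular snapshot", call. = FALSE)
    }
    keep <- rep(TRUE, nrow(snap$parts))
    for (con in vs$rule$constraints) {
      vals <- tolower(snap$parts[[con$part]])
      want <- tolower(con$value)
      keep <- keep & switch(con$op,
        equals = vals == want[1],
        `not-equals` = vals != want[1],
        `in` = vals %in% want,
        stop("unknown constraint operator: ", con$op, call. = FALSE)
      )
    }
    out <- data.frame(system = rep(snap$system, sum(keep)),
                      code = snap$parts$code[keep],
                      display = snap$concepts$display[keep],
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$system, out$code), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test value-set membership
#'
#' Decides whether a concept is in a value set without materializing the full
#' expansion: extensional sets by direct lookup, hierarchical rules by an
#' upward ancestor walk from the candidate code, tabular rules by a single
#' parts-row check. A concept whose code is unknown to the relevant snapshot
#' raises an `mf_unknown_concept` error (rather than returning `FALSE`) so
#' snapshot/fixture mismatches surface early.
#'
#' @inheritParams expand_valueset
#' @param concept An [concept_ref()].
#' @return Logical scalar.
#' @export
valueset_contains <- function(vs, concept, snapshots = default_snapshots()) {
  stopifnot(inherits(vs, "mf_valueset"), is_concept_ref(concept))
  if (vs$kind == "extensional") {
    return(any(vapply(vs$members, same_concept, logical(1), concept)))
  }
  if (!identical(concept$system, vs$rule$system)) return(FALSE)
  snap <- snapshot_for(snapshots, vs$rule$system)
  if (!has_concept(snap, concept$code)) {
    stop_unknown_concept(concept$code, snap$system)
  }
  if (vs$rule$dialect == "hierarchical") {
    anc <- ancestors(snap, concept$code)
    included <- any(vapply(vs$rule$include, function(inc) {
      inc$code %in% anc || (identical(inc$op, "<<") &&
                              identical(inc$code, concept$code))
    }, logical(1)))
    if (!included) return(FALSE)
    excluded <- any(vapply(vs$rule$exclude %||% character(0), function(exc) {
      identical(exc, concept$code) || exc %in% anc
    }, logical(1)))
    !excluded
  } else {
    row <- snap$parts[snap$parts$code == concept$code, , drop = FALSE]
    all(vapply(vs$rule$constraints, function(con) {
      vals <- tolower(row[[con$part]])
      want <- tolower(con$value)
      switch(con$op,
             equals = vals == want[1],
             `not-equals` = vals != want[1],
             `in` = vals %in% want)
    }, logical(1)))
  }
}

#' Load the value-set catalog
#'
#' Reads a YAML catalog of value-set definitions keyed by canonical URL. The
#' bundled catalog carries every value set the data model binds to: result
#' value sets (detected / positive styles), the organism hierarchy with its
#' five excluded kingdom subtrees, colony-count codes, the phenotypic
#' susceptibility-test rule, EUCAST and CLSI-style interpretation categories,
#' microscopy methods and staining procedures, MDRO-type hierarchies, MRGN
#' answer codes, resistance gene/mutation tests, virulence-factor tests,
#' serology tests, semiquantitative results, and the report study types.
#'
#' @param path Path to a catalog YAML; defaults to the bundled catalog.
#' @return Named list of `mf_valueset` keyed by canonical URL, with a
#'   `names` attribute index for short-name lookup; class `mf_catalog`.
#' @export
load_valueset_catalog <- function(path = system.file("extdata",
                                                     "valueset_catalog.yaml",
                                                     package = "microfhir")) {
  doc <- yaml::read_yaml(path)
  sets <- lapply(doc$valuesets, function(e) {
    if (e$kind == "extensional") {
      members <- lapply(e$members, function(m) {
        concept_ref(m$system, as.character(m$code), m$display)
      })
      valueset_def(e$url, "extensional", members = members, name = e$name)
    } else {
      rule <- e$rule
      if (!is.null(rule$include)) {
        rule$include <- lapply(rule$include, function(i) {
          list(op = i$op, code = as.character(i$code))
        })
      }
      if (!is.null(rule$exclude)) {
        rule$exclude <- as.character(unlist(rule$exclude))
      }
      if (!is.null(rule$constraints)) {
        rule$constraints <- lapply(rule$constraints, function(cn) {
          list(part = cn$part, op = cn$op, value = as.character(unlist(cn$value)))
        })
      }
      valueset_def(e$url, "intensional", rule = rule, name = e$name)
    }
  })
  names(sets) <- vapply(doc$valuesets, `[[`, character(1), "url")
  attr(sets, "by_name") <- stats::setNames(
    names(sets), vapply(doc$valuesets, `[[`, character(1), "name"))
  class(sets) <- "mf_catalog"
  sets
}

#' Look up a value set in a catalog
#'
#' @param catalog An `mf_catalog` from [load_valueset_catalog()].
#' @param id Canonical URL or short name.
#' @return The `mf_valueset`.
#' @export
catalog_vs <- function(catalog, id) {
  vs <- catalog[[id]]
  if (is.null(vs)) {
    url <- attr(catalog, "by_name")[[id]]
    if (!is.null(url)) vs <- catalog[[url]]
  }
  if (is.null(vs)) stop("value set not in catalog: ", id, call. = FALSE)
  vs
}

#' @export
print.mf_catalog <- function(x, ...) {
  cat(sprintf("<valueset catalog: %d value sets>\n", length(x)))
  invisible(x)
}

# Memoized default catalog/snapshots for the common call pattern.
the <- new.env(parent = emptyenv())

#' Bundled value-set catalog
#' @return The catalog shipped with the package (cached after first load).
#' @export
default_catalog <- function() {
  if (is.null(the$catalog)) the$catalog <- load_valueset_catalog()
  the$catalog
}

#' @rdname default_catalog
#' @export
cached_snapshots <- function() {
  if (is.null(the$snapshots)) the$snapshots <- default_snapshots()
  the$snapshots
}
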