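#' Load a terminology snapshot
#'
#' Reads a flat-file snapshot of a code system into memory. Two dialects are
#' supported. A *hierarchical* snapshot (SNOMED CT-like) is a TSV with columns
#' `code`, `display`, `parent_codes` (pipe-separated list of parents, empty
#' for roots); the is-a graph must be acyclic and every parent must itself be
#' declared. A *tabular* snapshot (LOINC-like) is a TSV with columns `code`,
#' `display`, `property`, `method`, `class`, `component` carrying the
#' multi-axial parts each code is composed of.
#'
#' @param path Path to the TSV file.
#' @param dialect `"hierarchical"` or `"tabular"`.
#' @param system Code-system key or URI the snapshot belongs to.
#' @param version Free-text snapshot version label.
#' @return Object of class `term_snapshot`.
#' @export
#' @examples
#' snap <- load_snapshot(
#'   system.file("extdata", "snomed_mini.tsv", package = "microfhir"),
#'   dialect = "hierarchical", system = "snomed")
#' nrow(snap$concepts)
load_snapshot <- function(path, dialect = c("hierarchical", "tabular"),
                          system, version = "fixture") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("snapshot file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, colClasses = "character", quote = "",
                           comment.char = "", fileEncoding = "UTF-8",
                           check.names = TRUE)
  required <- if (dialect == "hierarchical") {
    c("code", "display", "parent_codes")
  } else {
    c("code", "display", "property", "method", "class", "component")
  }
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("snapshot ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!nzchar(tab$code) | grepl("\\s", tab$code))
  if (length(bad)) {
    stop(sprintf("malformed snapshot row %d (line %d): empty or blank code",
                 bad[1], bad[1] + 1L), call. = FALSE)
  }
  if (anyDuplicated(tab$code)) {
    dup <- tab$code[duplicated(tab$code)][1]
    stop("duplicate concept code in snapshot: ", dup, call. = FALSE)
  }
  snap <- list(system = resolve_system(system), dialect = dialect,
               version = version,
               concepts = data.frame(code = tab$code, display = tab$display,
                                     stringsAsFactors = FALSE))
  if (dialect == "hierarchical") {
    parents <- strsplit(tab$parent_codes, "|", fixed = TRUE)
    parents <- lapply(parents, function(p) p[nzchar(p)])
    edges <- data.frame(
      parent = unlist(parents, use.names = FALSE),
      child = rep(tab$code, lengths(parents)),
      stringsAsFactors = FALSE
    )
    unknown <- setdiff(edges$parent, tab$code)
    if (length(unknown)) {
      stop("edge references undeclared concept: ", unknown[1], call. = FALSE)
    }
    check_acyclic(edges, tab$code)
    snap$edges <- edges
    snap$children <- split(edges$child, factor(edges$parent, levels = tab$code))
    snap$parents <- split(edges$parent, factor(edges$child, levels = tab$code))
  } else {
    snap$parts <- data.frame(
      code = tab$code, property = tab$property, method = tab$method,
      class = tab$class, component = tab$component, stringsAsFactors = FALSE
    )
  }
  structure(snap, class = "term_snapshot")
}

# Kahn topological sort; names one member of a cycle if one exists.
check_acyclic <- function(edges, codes) {
  indeg <- stats::setNames(integer(length(codes)), codes)
  tbl <- table(edges$child)
  indeg[names(tbl)] <- as.integer(tbl)
  children <- split(edges$child, factor(edges$parent, levels = codes))
  queue <- codes[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    node <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (ch in children[[node]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(codes)) {
    member <- names(indeg)[indeg > 0L][1]
    stop("is-a graph contains a cycle involving concept ", member,
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.term_snapshot <- function(x, ...) {
  cat(sprintf("<term_snapshot %s: %d concepts, %s dialect, version %s>\n",
              x$system, nrow(x$concepts), x$dialect, x$version))
  invisible(x)
}

has_concept <- function(snapshot, code) code %in% snapshot$concepts$code

display_of <- function(snapshot, code) {
  i <- match(code, snapshot$concepts$code)
  snapshot$concepts$display[i]
}

#' Transitive descendants of a concept
#'
#' Computes the set of codes reachable from `root` through is-a child edges
#' (the `<` / `<<` operators of the supported ECL subset).
#'
#' @param snapshot A hierarchical `term_snapshot`.
#' @param root Code whose subtree is wanted.
#' @param include_self Include `root` itself (`<<` semantics)?
#' @return Character vector of codes (unordered set).
#' @export
descendants <- function(snapshot, root, include_self = FALSE) {
  stopifnot(inherits(snapshot, "term_snapshot"))
  if (snapshot$dialect != "hierarchical") {
    stop("descendants() requires a hierarchical snapshot", call. = FALSE)
  }
  if (!has_concept(snapshot, root)) {
    stop_unknown_concept(root, snapshot$system)
  }
  out <- character(0)
  frontier <- snapshot$children[[root]]
  seen <- new.env(parent = emptyenv())
  while (length(frontier)) {
    fresh <- frontier[!vapply(frontier, exists, logical(1), envir = seen)]
    for (code in fresh) assign(code, TRUE, envir = seen)
    out <- c(out, fresh)
    frontier <- unlist(lapply(fresh, function(c) snapshot$children[[c]]),
                       use.names = FALSE)
  }
  out <- unique(out)
  if (include_self) out <- unique(c(root, out))
  out
}

# Upward walk: all ancestors of a code (not including itself).
ancestors <- function(snapshot, code) {
  out <- character(0)
  frontier <- snapshot$parents[[code]]
  while (length(frontier)) {
    frontier <- setdiff(unique(frontier), out)
    out <- c(out, frontier)
    frontier <- unlist(lapply(frontier, function(c) snapshot$parents[[c]]),
                       use.names = FALSE)
  }
  out
}

# TRUE when `code` lies under `root` (strict or not) without materializing
# the full subtree.
is_descendant <- function(snapshot, code, root, include_self = FALSE) {
  if (include_self && identical(code, root)) return(TRUE)
  root %in% ancestors(snapshot, code)
}

stop_unknown_concept <- function(code, system) {
  stop(structure(
    class = c("mf_unknown_concept", "error", "condition"),
    list(message = sprintf("unknown concept %s in system %s", code, system),
         call = NULL)
  ))
}

#' Bundled fixture snapshots
#'
#' Loads the two snapshot fixtures shipped with the package: a SNOMED CT-like
#' hierarchical toy graph and a LOINC-like parts table. The fixtures contain
#' the codes the data model binds to, wired into a deliberately small toy
#' hierarchy; codes in the 99xxxxxxx / 99xxx-x ranges are synthetic and must
#' not be mistaken for released terminology content.
#'
#' @param dir Directory holding `snomed_mini.tsv` and `loinc_mini.tsv`;
#'   defaults to the copies installed with the package.
#' @return Named list of `term_snapshot` objects keyed by system URI.
#' @export
default_snapshots <- function(dir = system.file("extdata", package = "microfhir")) {
  snomed <- load_snapshot(file.path(dir, "snomed_mini.tsv"),
                          dialect = "hierarchical", system = "snomed")
  loinc <- load_snapshot(file.path(dir, "loinc_mini.tsv"),
                         dialect = "tabular", system = "loinc")
  out <- list(snomed, loinc)
  names(out) <- vapply(out, `[[`, character(1), "system")
  out
}
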