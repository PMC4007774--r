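#' Construct an icon
#'
#' An icon is an assignment of primitives to components: a named list
#' mapping component ids to character vectors of primitive ids. Empty
#' optional slots may simply be absent.
#'
#' @param id icon identifier.
#' @param assignment named list, `component_id -> character vector` of
#'   primitive ids.
#' @return An object of class `vcm_icon`.
#' @export
icon <- function(id, assignment) {
  stopifnot(is.character(id), length(id) == 1L, is.list(assignment))
  if (is.null(names(assignment)) || any(names(assignment) == "")) {
    stop("assignment must be a named list keyed by component_id")
  }
  assignment <- lapply(assignment, function(x) sort(unique(as.character(x))))
  assignment <- assignment[order(names(assignment))]
  structure(list(id = id, assignment = assignment), class = "vcm_icon")
}

#' @export
print.vcm_icon <- function(x, ...) {
  cat("Icon <", x$id, ">\n", sep = "")
  for (comp in names(x$assignment)) {
    cat("  ", comp, ": ", paste(x$assignment[[comp]], collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Flattened primitive set of an icon
#'
#' The union of all component assignments. Its cardinality is the
#' per-icon term in the denominator of both Dice coefficients.
#'
#' @param icon a `vcm_icon`.
#' @return Sorted character vector of primitive ids.
#' @export
primitives_of <- function(icon) {
  stopifnot(inherits(icon, "vcm_icon"))
  sort(unique(unlist(icon$assignment, use.names = FALSE)))
}

#' Structural validation of an icon
#'
#' Checks the arity rules of the iconic language: required components
#' (central colour, shape) are non-empty, single-valued components carry
#' at most one primitive, every referenced primitive exists in the
#' hierarchy and sits in the component it is assigned to, and the
#' flattened primitive set is non-empty. The full combinatory grammar of
#' the language (forbidden combinations) is out of scope.
#'
#' @param icon a `vcm_icon`.
#' @param hierarchy a `primitive_hierarchy`.
#' @param components a `component_table`.
#' @return Character vector of violations; empty (`character(0)`) when the
#'   icon is structurally valid.
#' @export
validate_icon <- function(icon, hierarchy, components) {
  stopifnot(inherits(icon, "vcm_icon"),
            inherits(hierarchy, "primitive_hierarchy"),
            inherits(components, "component_table"))
  violations <- character(0)
  known_comp <- components$component_id
  unknown_comp <- setdiff(names(icon$assignment), known_comp)
  for (comp in unknown_comp) {
    violations <- c(violations, paste0("unknown component: ", comp))
  }
  for (i in seq_len(nrow(components))) {
    comp <- components$component_id[i]
    prims <- icon$assignment[[comp]]
    n <- length(prims)
    if (components$required[i] && n == 0L) {
      violations <- c(violations,
                      paste0("required component empty: ", comp))
    }
    if (!components$multi_valued[i] && n > 1L) {
      violations <- c(violations,
                      paste0("single-valued component holds ", n,
                             " primitives: ", comp))
    }
    if (n > 0L) {
      bad <- prims[!(prims %in% names(hierarchy$component))]
      for (p in bad) {
        violations <- c(violations, paste0("unknown primitive: ", p))
      }
      ok <- setdiff(prims, bad)
      wrong <- ok[hierarchy$component[ok] != comp]
      for (p in wrong) {
        violations <- c(violations,
                        paste0("primitive ", p, " belongs to component ",
                               hierarchy$component[[p]], ", not ", comp))
      }
    }
  }
  if (length(primitives_of(icon)) == 0L) {
    violations <- c(violations, "icon has no primitives")
  }
  violations
}

#' Exact icon identity
#'
#' Two icons are identical iff their per-component primitive sets are
#' equal — the definition underlying binary concordance. No semantic
#' tolerance is applied.
#'
#' @param a,b `vcm_icon` objects.
#' @return `TRUE` or `FALSE`.
#' @export
icons_identical <- function(a, b) {
  stopifnot(inherits(a, "vcm_icon"), inherits(b, "vcm_icon"))
  slots_a <- Filter(length, a$assignment)
  slots_b <- Filter(length, b$assignment)
  if (!identical(sort(names(slots_a)), sort(names(slots_b)))) return(FALSE)
  all(vapply(names(slots_a),
             function(cmp) identical(slots_a[[cmp]], slots_b[[cmp]]),
             logical(1)))
}

#' Bundle icons into a keyed set
#'
#' @param ... `vcm_icon` objects (or a single list of them).
#' @return A named list of class `icon_set`, keyed by icon id.
#' @export
icon_set <- function(...) {
  icons <- list(...)
  if (length(icons) == 1L && !inherits(icons[[1]], "vcm_icon")) {
    icons <- icons[[1]]
  }
  stopifnot(all(vapply(icons, inherits, logical(1), "vcm_icon")))
  ids <- vapply(icons, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate icon id: ", paste(unique(ids[duplicated(ids)]),
                                      collapse = ", "))
  }
  names(icons) <- ids
  structure(icons, class = "icon_set")
}

#' @export
print.icon_set <- function(x, ...) {
  cat("Icon set with", length(x), "icons\n")
  invisible(x)
}
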