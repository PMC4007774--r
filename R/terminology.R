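#' Construct a terminology
#'
#' A terminology is a set of coded concepts arranged in a hierarchy
#' (mono-hierarchic: every non-root concept has exactly one parent;
#' poly-hierarchic: at least one), plus concept-to-icon alignment records
#' carrying a provenance flag (`manual` for expert-made alignments,
#' `automatic` for alignments inherited from an ancestor). Concepts may
#' carry cross-terminology identifiers (CUI-like) used for pairing.
#'
#' @param id terminology identifier.
#' @param hierarchy_kind `"mono"` or `"poly"`.
#' @param concepts `data.frame` with columns `code`, `label`, and
#'   list-columns `parents` and `cross_ids` (character vectors; empty for
#'   roots / unlinked concepts).
#' @param alignments `data.frame` with columns `code`, `icon_id`,
#'   `provenance` (`"manual"` or `"automatic"`); may have zero rows.
#' @param icons optional `icon_set`; when supplied, alignment icon ids
#'   must resolve in it.
#' @return An object of class `terminology`.
#' @export
terminology <- function(id, hierarchy_kind = c("poly", "mono"),
                        concepts, alignments = NULL, icons = NULL) {
  hierarchy_kind <- match.arg(hierarchy_kind)
  concepts <- as.data.frame(concepts, stringsAsFactors = FALSE)
  stopifnot(all(c("code", "label", "parents", "cross_ids") %in%
                  names(concepts)))
  if (anyDuplicated(concepts$code)) {
    stop("duplicate concept code: ",
         paste(unique(concepts$code[duplicated(concepts$code)]),
               collapse = ", "))
  }
  codes <- concepts$code
  parents <- concepts$parents
  for (i in seq_along(codes)) {
    p <- parents[[i]]
    dangling <- setdiff(p, codes)
    if (length(dangling) > 0) {
      stop("concept ", codes[i], " references unknown parent: ",
           paste(dangling, collapse = ", "))
    }
    if (hierarchy_kind == "mono" && length(p) > 1L) {
      stop("concept ", codes[i], " has ", length(p),
           " parents in a mono-hierarchic terminology")
    }
  }
  check_acyclic(codes, parents)
  if (is.null(alignments)) {
    alignments <- data.frame(code = character(0), icon_id = character(0),
                             provenance = character(0),
                             stringsAsFactors = FALSE)
  }
  alignments <- as.data.frame(alignments, stringsAsFactors = FALSE)
  stopifnot(all(c("code", "icon_id", "provenance") %in% names(alignments)))
  bad_code <- setdiff(alignments$code, codes)
  if (length(bad_code) > 0) {
    stop("alignment references unknown concept: ",
         paste(bad_code, collapse = ", "))
  }
  bad_prov <- setdiff(alignments$provenance, c("manual", "automatic"))
  if (length(bad_prov) > 0) {
    stop("invalid provenance: ", paste(bad_prov, collapse = ", "))
  }
  if (!is.null(icons)) {
    bad_icon <- setdiff(alignments$icon_id, names(icons))
    if (length(bad_icon) > 0) {
      stop("alignment references unknown icon: ",
           paste(bad_icon, collapse = ", "))
    }
  }
  alignments <- unique(alignments)
  rownames(alignments) <- NULL
  structure(
    list(id = id, hierarchy_kind = hierarchy_kind, concepts = concepts,
         alignments = alignments),
    class = "terminology"
  )
}

# Kahn-style check: repeatedly peel concepts whose parents are all peeled.
check_acyclic <- function(codes, parents) {
  remaining <- codes
  repeat {
    n_par <- vapply(parents[match(remaining, codes)],
                    function(p) length(intersect(p, remaining)),
                    integer(1))
    leaves <- remaining[n_par == 0L]
    if (length(leaves) == 0L) break
    remaining <- setdiff(remaining, leaves)
  }
  if (length(remaining) > 0) {
    stop("cycle in concept hierarchy involving: ",
         paste(head(remaining, 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.terminology <- function(x, ...) {
  cat("Terminology <", x$id, "> (", x$hierarchy_kind, "-hierarchic): ",
      nrow(x$concepts), " concepts, ", nrow(x$alignments),
      " alignment records (", sum(x$alignments$provenance == "manual"),
      " manual)\n", sep = "")
  invisible(x)
}

#' Icon ids aligned to a concept
#'
#' @param t a `terminology`.
#' @param code concept code.
#' @param provenance optionally restrict to `"manual"` or `"automatic"`.
#' @return Sorted character vector of icon ids (possibly empty).
#' @export
aligned_icons <- function(t, code, provenance = NULL) {
  a <- t$alignments
  keep <- a$code == code
  if (!is.null(provenance)) keep <- keep & a$provenance == provenance
  sort(unique(a$icon_id[keep]))
}

#' Closest-ancestor icon inheritance
#'
#' Concepts without a manual alignment inherit icons from their closest
#' manually aligned ancestor(s), where distance is the number of parent
#' edges walked upward (breadth-first over all parents in a
#' poly-hierarchy). Only manual records are inheritance sources — icons
#' never chain through automatic records. When several manually aligned
#' ancestors tie at the minimal distance, the union of their icon sets is
#' inherited, deduplicated. Concepts with no manually aligned ancestor
#' stay unaligned. Manual records are never modified, and the procedure
#' is idempotent: automatic records are recomputed as a pure function of
#' the manual ones.
#'
#' @param t a `terminology` with at least one manual alignment record.
#' @return The terminology with automatic records added.
#' @export
inherit_icons <- function(t) {
  stopifnot(inherits(t, "terminology"))
  codes <- t$concepts$code
  parents <- t$concepts$parents
  names(parents) <- codes
  manual <- t$alignments[t$alignments$provenance == "manual", , drop = FALSE]
  manual_codes <- unique(manual$code)
  auto <- list()
  for (code in setdiff(codes, manual_codes)) {
    sources <- closest_manual_ancestors(code, parents, manual_codes)
    if (length(sources) == 0L) next
    icons <- sort(unique(manual$icon_id[manual$code %in% sources]))
    auto[[code]] <- data.frame(code = code, icon_id = icons,
                               provenance = "automatic",
                               stringsAsFactors = FALSE)
  }
  new_align <- rbind(manual, do.call(rbind, auto))
  rownames(new_align) <- NULL
  t$alignments <- new_align
  t
}

# Upward BFS: frontier of ancestors at distance d = 1, 2, ...; stop at the
# first distance containing a manually aligned concept.
closest_manual_ancestors <- function(code, parents, manual_codes) {
  visited <- code
  frontier <- unique(unlist(parents[code], use.names = FALSE))
  frontier <- setdiff(frontier, visited)
  while (length(frontier) > 0L) {
    hits <- intersect(frontier, manual_codes)
    if (length(hits) > 0L) return(sort(hits))
    visited <- c(visited, frontier)
    frontier <- unique(unlist(parents[frontier], use.names = FALSE))
    frontier <- setdiff(frontier, visited)
  }
  character(0)
}

#' Pair concepts across two terminologies by shared cross identifiers
#'
#' Emits one pair for every combination of a concept in `a` and a concept
#' in `b` sharing at least one cross identifier (cartesian per shared
#' id), deduplicated so a pair appears once even when it shares several
#' ids, and sorted by codes for determinism.
#'
#' @param a,b `terminology` objects.
#' @return `data.frame` with columns `code_a`, `code_b`, `cross_id` (one
#'   of the shared ids, the lexicographically first).
#' @export
pair_by_cross_id <- function(a, b) {
  expand <- function(t) {
    n <- lengths(t$concepts$cross_ids)
    data.frame(code = rep(t$concepts$code, n),
               cross_id = unlist(t$concepts$cross_ids, use.names = FALSE),
               stringsAsFactors = FALSE)
  }
  ea <- expand(a)
  eb <- expand(b)
  m <- merge(ea, eb, by = "cross_id", suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) {
    return(data.frame(code_a = character(0), code_b = character(0),
                      cross_id = character(0), stringsAsFactors = FALSE))
  }
  m <- m[order(m$code_a, m$code_b, m$cross_id), ]
  m <- m[!duplicated(m[, c("code_a", "code_b")]), ]
  rownames(m) <- NULL
  m[, c("code_a", "code_b", "cross_id")]
}
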