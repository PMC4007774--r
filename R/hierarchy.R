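ROOT_ID <- "ROOT"

#' Construct the component table of an iconic language
#'
#' An icon is a combination of slots ("components"), each filled by zero or
#' more primitives. The modelled language has five components: central
#' colour, shape, central pictogram, top-right colour and top-right
#' pictogram. Central colour and shape are required; the others may be
#' empty. Whether a component admits more than one primitive is
#' configuration, not a constant of the language.
#'
#' @param component_id character vector of unique component identifiers.
#' @param name human-readable labels (defaults to the identifiers).
#' @param required logical; must a valid icon fill this slot?
#' @param multi_valued logical; may the slot hold more than one primitive?
#' @return A `data.frame` of class `component_table`.
#' @export
component_table <- function(component_id, name = component_id,
                            required = FALSE, multi_valued = FALSE) {
  stopifnot(is.character(component_id), !anyDuplicated(component_id))
  out <- data.frame(
    component_id = component_id,
    name = name,
    required = as.logical(required),
    multi_valued = as.logical(multi_valued),
    stringsAsFactors = FALSE
  )
  class(out) <- c("component_table", "data.frame")
  out
}

#' Default five-component configuration
#'
#' Central colour and shape are required and single-valued; the central
#' pictogram slot is multi-valued (anatomy plus a qualifier such as
#' inflammation may co-occur); the two top-right slots are optional and
#' single-valued.
#'
#' @return A `component_table` with five rows.
#' @export
default_components <- function() {
  component_table(
    component_id = c("central_color", "shape", "central_pictogram",
                     "topright_color", "topright_pictogram"),
    name = c("Central color", "Shape", "Central pictogram",
             "Top-right color", "Top-right pictogram"),
    required = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    multi_valued = c(FALSE, FALSE, TRUE, FALSE, FALSE)
  )
}

#' Build a primitive hierarchy
#'
#' Primitives are the atomic building blocks of icons (colours, shapes,
#' pictograms), organised in a rooted tree at most six levels deep. A
#' single virtual root (`"ROOT"`) spans all components, so two primitives
#' from different components share only the root — which is what drives
#' their Lin similarity to zero. Every primitive has exactly one parent;
#' within a component every ancestor chain stays in that component.
#'
#' @param primitives a `data.frame` with columns `primitive_id`, `label`,
#'   `component_id`, `parent_id`; top-level primitives use `"ROOT"` as
#'   parent.
#' @param max_depth maximum allowed depth below the root (default 6).
#' @return An object of class `primitive_hierarchy` with precomputed
#'   self-inclusive ancestor closures (each closure ends at `"ROOT"`).
#' @export
primitive_hierarchy <- function(primitives, max_depth = 6L) {
  req <- c("primitive_id", "label", "component_id", "parent_id")
  if (!all(req %in% names(primitives))) {
    stop("primitives table must have columns: ", paste(req, collapse = ", "))
  }
  primitives <- as.data.frame(primitives, stringsAsFactors = FALSE)
  ids <- primitives$primitive_id
  if (anyDuplicated(ids)) {
    stop("duplicate primitive_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (ROOT_ID %in% ids) stop("'ROOT' is reserved for the virtual root")
  parent <- primitives$parent_id
  names(parent) <- ids
  component <- primitives$component_id
  names(component) <- ids
  unknown <- setdiff(parent, c(ids, ROOT_ID))
  if (length(unknown) > 0) {
    stop("unknown parent_id: ", paste(unknown, collapse = ", "))
  }
  # walk every chain up to ROOT; detects cycles and over-deep chains
  ancestors <- vector("list", length(ids))
  names(ancestors) <- ids
  depth <- integer(length(ids))
  names(depth) <- ids
  for (id in ids) {
    chain <- id
    cur <- id
    while (parent[[cur]] != ROOT_ID) {
      cur <- parent[[cur]]
      if (cur %in% chain) stop("cycle in primitive hierarchy at: ", id)
      if (component[[cur]] != component[[id]]) {
        stop("primitive ", id, " has ancestor ", cur,
             " from a different component")
      }
      chain <- c(chain, cur)
    }
    if (length(chain) > max_depth) {
      stop("primitive ", id, " is deeper than max_depth = ", max_depth)
    }
    depth[[id]] <- length(chain)
    ancestors[[id]] <- c(chain, ROOT_ID)
  }
  structure(
    list(primitives = primitives, parent = parent, component = component,
         ancestors = ancestors, depth = depth, root = ROOT_ID,
         max_depth = as.integer(max_depth)),
    class = "primitive_hierarchy"
  )
}

#' @export
print.primitive_hierarchy <- function(x, ...) {
  cat("Primitive hierarchy: ", nrow(x$primitives), " primitives, ",
      length(unique(x$component)), " components, max depth ",
      max(x$depth), "\n", sep = "")
  invisible(x)
}

#' Self-inclusive ancestor closure of a primitive
#'
#' The closure contains the primitive itself, every ancestor up its parent
#' chain, and always the virtual root. Self-inclusion makes the Lin
#' similarity of a primitive with itself equal 1 without special-casing.
#'
#' @param h a `primitive_hierarchy`.
#' @param id a primitive id (or `"ROOT"`).
#' @return Character vector of primitive ids, ordered from `id` to `"ROOT"`.
#' @export
primitive_ancestors <- function(h, id) {
  if (identical(id, ROOT_ID)) return(ROOT_ID)
  anc <- h$ancestors[[id]]
  if (is.null(anc)) stop("unknown primitive: ", id)
  anc
}

#' Shared ancestors of two primitives
#'
#' Intersection of the two self-inclusive ancestor closures. Always
#' contains the root; contains `p` iff `p` is an ancestor-or-self of `q`.
#' Primitives from different components share only the virtual root.
#'
#' @param p,q primitive ids.
#' @param h a `primitive_hierarchy`.
#' @return Character vector of shared ancestor ids (including `"ROOT"`).
#' @export
shared_ancestors <- function(p, q, h) {
  intersect(primitive_ancestors(h, p), primitive_ancestors(h, q))
}
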