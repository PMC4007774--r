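#' Corpus probabilities over primitives (information-content model)
#'
#' Builds the occurrence probability `p(Pr)` of every primitive from a
#' table of direct occurrence counts, using cumulative
#' (descendant-inclusive) counting: each occurrence of a primitive counts
#' toward the primitive itself and all of its ancestors, so `p` is
#' monotone non-decreasing towards the root and `p(ROOT) = 1` exactly.
#' That normalisation is what makes Lin similarity hit 0 precisely when
#' two primitives share only the virtual root.
#'
#' @param direct_counts named numeric vector of direct occurrence counts
#'   per primitive id; primitives absent from the vector count 0.
#' @param hierarchy a `primitive_hierarchy`.
#' @param smooth additive smoothing applied to every primitive's direct
#'   count (default 1, so no primitive ever has probability 0 and logs
#'   are always defined; use 0 for raw counts).
#' @return An object of class `corpus_probabilities` with elements
#'   `direct` (smoothed direct counts), `cumulative`, `total`, and `p`
#'   (probabilities, including `p["ROOT"] = 1`).
#' @export
corpus_probabilities <- function(direct_counts, hierarchy, smooth = 1) {
  stopifnot(inherits(hierarchy, "primitive_hierarchy"))
  ids <- hierarchy$primitives$primitive_id
  unknown <- setdiff(names(direct_counts), ids)
  if (length(unknown) > 0) {
    stop("counts for unknown primitives: ", paste(unknown, collapse = ", "))
  }
  direct <- stats::setNames(rep(smooth, length(ids)), ids)
  direct[names(direct_counts)] <- direct[names(direct_counts)] +
    as.numeric(direct_counts)
  total <- sum(direct)
  if (total <= 0) stop("empty corpus: total occurrence count is 0")
  cumulative <- stats::setNames(numeric(length(ids)), ids)
  for (id in ids) {
    anc <- setdiff(hierarchy$ancestors[[id]], ROOT_ID)
    cumulative[anc] <- cumulative[anc] + direct[[id]]
  }
  p <- c(cumulative / total, stats::setNames(1, ROOT_ID))
  structure(list(direct = direct, cumulative = cumulative, total = total,
                 p = p),
            class = "corpus_probabilities")
}

#' @export
print.corpus_probabilities <- function(x, ...) {
  cat("Corpus probabilities over", length(x$direct), "primitives;",
      "total occurrences:", x$total, "\n")
  invisible(x)
}

#' Corpus probabilities from alignment relations
#'
#' The reference corpus is the entire set of concept-to-icon alignment
#' records across the supplied terminologies: each record contributes one
#' occurrence of every primitive of its icon (an icon aligned to k
#' concepts counts k times under the default `"per_relation"` weighting;
#' `"per_icon"` counts each distinct aligned icon once).
#'
#' @param terminologies list of `terminology` objects.
#' @param icons an `icon_set` resolving every aligned icon id.
#' @param hierarchy a `primitive_hierarchy`.
#' @param weighting `"per_relation"` (default) or `"per_icon"`.
#' @param smooth additive smoothing on direct counts (default 1).
#' @return A `corpus_probabilities` object.
#' @export
build_corpus_probabilities <- function(terminologies, icons, hierarchy,
                                       weighting = c("per_relation",
                                                     "per_icon"),
                                       smooth = 1) {
  weighting <- match.arg(weighting)
  if (inherits(terminologies, "terminology")) {
    terminologies <- list(terminologies)
  }
  icon_ids <- unlist(lapply(terminologies,
                            function(t) t$alignments$icon_id),
                     use.names = FALSE)
  if (length(icon_ids) == 0L) stop("empty corpus: no alignment records")
  if (weighting == "per_icon") icon_ids <- unique(icon_ids)
  missing_ic <- setdiff(icon_ids, names(icons))
  if (length(missing_ic) > 0) {
    stop("alignments reference unknown icons: ",
         paste(unique(missing_ic), collapse = ", "))
  }
  prims <- unlist(lapply(icon_ids, function(i) primitives_of(icons[[i]])),
                  use.names = FALSE)
  counts <- table(prims)
  corpus_probabilities(stats::setNames(as.numeric(counts), names(counts)),
                       hierarchy, smooth = smooth)
}

#' Lin information-content similarity between two primitives
#'
#' `sim(p, q) = max over shared ancestors a of 2 log p(a) /
#' (log p(p) + log p(q))`: the maximising ancestor is the most
#' informative common ancestor (smallest corpus probability). The value
#' lies in `[0, 1]`: 1 when `p = q`, 0 when the only common ancestor is
#' the root. The natural logarithm is used internally; the ratio makes
#' the result base-free. When both arguments have probability 1 the
#' degenerate `0/0` is resolved as 1 for identical primitives and 0
#' otherwise.
#'
#' @param p,q primitive ids.
#' @param probs a `corpus_probabilities` built on the same hierarchy.
#' @param h a `primitive_hierarchy`.
#' @return Similarity value in `[0, 1]`.
#' @export
lin_similarity <- function(p, q, probs, h) {
  if (!(p %in% names(probs$p))) stop("unknown primitive: ", p)
  if (!(q %in% names(probs$p))) stop("unknown primitive: ", q)
  denom <- log(probs$p[[p]]) + log(probs$p[[q]])
  if (denom == 0) return(if (identical(p, q)) 1 else 0)
  shared <- shared_ancestors(p, q, h)
  max(2 * log(probs$p[shared]) / denom)
}

#' Similarity source backed by a corpus (Lin)
#'
#' @param probs a `corpus_probabilities`.
#' @param h the matching `primitive_hierarchy`.
#' @return A function `(p, q) -> similarity` for use with
#'   [dsc_semantic()].
#' @export
lin_sim_fun <- function(probs, h) {
  force(probs); force(h)
  function(p, q) lin_similarity(p, q, probs, h)
}

#' Similarity source backed by an explicit pair table
#'
#' Used for worked-example mode, where printed pairwise similarities are
#' inputs. The symmetric closure of the table is applied; identical
#' primitives score 1 regardless of the table. Pairs absent from the
#' table score 0 by default (cross-component pairs in the worked example
#' are implicit zeros) or raise an error under `missing = "error"`.
#'
#' @param table `data.frame` with columns `primitive_a`, `primitive_b`,
#'   `similarity`.
#' @param missing `"zero"` (default) or `"error"`.
#' @return A function `(p, q) -> similarity`.
#' @export
fixture_sim_fun <- function(table, missing = c("zero", "error")) {
  missing <- match.arg(missing)
  stopifnot(all(c("primitive_a", "primitive_b", "similarity") %in%
                  names(table)))
  key <- function(p, q) paste(p, q, sep = "\r")
  lut <- stats::setNames(
    c(table$similarity, table$similarity),
    c(key(table$primitive_a, table$primitive_b),
      key(table$primitive_b, table$primitive_a))
  )
  function(p, q) {
    if (identical(p, q)) return(1)
    k <- key(p, q)
    if (k %in% names(lut)) return(unname(lut[[k]]))
    if (missing == "error") {
      stop("no fixture similarity for pair (", p, ", ", q, ")")
    }
    0
  }
}

#' Crude Dice similarity coefficient between two icons
#'
#' `DSC_crude(I1, I2) = 2 |Pr(I1) ∩ Pr(I2)| / (|Pr(I1)| + |Pr(I2)|)`,
#' an exact set-overlap measure on the flattened primitive sets.
#'
#' @param a,b `vcm_icon` objects.
#' @return Coefficient in `[0, 1]`.
#' @export
dsc_crude <- function(a, b) {
  pa <- primitives_of(a)
  pb <- primitives_of(b)
  denom <- length(pa) + length(pb)
  if (denom == 0L) stop("both icons have empty primitive sets")
  2 * length(intersect(pa, pb)) / denom
}

#' Semantic Dice similarity coefficient between two icons
#'
#' Replaces the exact intersection of the crude Dice with best-match
#' semantic similarities: every primitive of each icon contributes its
#' best similarity against the other icon's primitive set, and the sum of
#' both directions is divided by the crude denominator
#' `|Pr(I1)| + |Pr(I2)|`. With a similarity source satisfying
#' `sim(x, x) = 1` and `sim >= 0` this is always at least the crude
#' coefficient.
#'
#' @param a,b `vcm_icon` objects.
#' @param sim a similarity source: function `(p, q) -> value in [0, 1]`,
#'   e.g. [lin_sim_fun()] or [fixture_sim_fun()].
#' @return Coefficient in `[0, 1]`.
#' @export
dsc_semantic <- function(a, b, sim) {
  pa <- primitives_of(a)
  pb <- primitives_of(b)
  denom <- length(pa) + length(pb)
  if (denom == 0L) stop("both icons have empty primitive sets")
  best <- function(p, others) max(vapply(others, function(q) sim(p, q),
                                         numeric(1)))
  num <- sum(vapply(pa, best, numeric(1), others = pb)) +
    sum(vapply(pb, best, numeric(1), others = pa))
  num / denom
}

#' Binary concordance between two icons
#'
#' Delegates to [icons_identical()]: a pair is concordant iff the two
#' icons are exactly identical.
#'
#' @param a,b `vcm_icon` objects.
#' @return `TRUE` or `FALSE`.
#' @export
concordant <- function(a, b) icons_identical(a, b)
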