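#' Configuration for the synthetic world generator
#'
#' Defaults emulate the modelled study conditions: a primitive hierarchy
#' of 221 primitives across 5 components with at most 6 levels; a
#' poly-hierarchic terminology up to 11 levels deep and a shallower
#' mono-hierarchic one; partial cross-linking; manual alignments on
#' one third of the cross-linked concepts (the rest inherit); and a
#' per-pair discordance rate of 0.25 applied as a single primitive
#' substitution.
#'
#' @param seed integer seed; identical seeds reproduce identical worlds.
#' @param n_primitives total primitives in the hierarchy.
#' @param max_primitive_depth maximum levels below the virtual root.
#' @param n_concepts_a,n_concepts_b concept counts of the poly (a) and
#'   mono (b) terminologies.
#' @param poly_parent_prob probability a concept in terminology a gains a
#'   second parent.
#' @param manual_fraction fraction of cross-linked concepts in a whose
#'   alignment is manual (the rest inherit from a manual ancestor).
#' @param crosslink_fraction fraction of the smaller terminology's
#'   concepts receiving a cross-link identifier.
#' @param discordance_rate probability that a cross-linked pair's
#'   mono-side icon is perturbed (one primitive substituted).
#' @param perturbation_kind `"sibling_swap"` (replace a primitive by a
#'   random sibling) or `"parent_generalization"` (replace it by its
#'   parent).
#' @param multi_icon_fraction probability that an aligned concept (a
#'   manual anchor on the poly side, a linked concept on the mono side)
#'   carries a second icon; such pairs are later removed by the
#'   single-icon filter, emulating the observed multi-icon alignments.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_primitives = 221L,
                             max_primitive_depth = 6L,
                             n_concepts_a = 800L,
                             n_concepts_b = 800L,
                             poly_parent_prob = 0.15,
                             manual_fraction = 0.33,
                             crosslink_fraction = 0.8,
                             discordance_rate = 0.25,
                             perturbation_kind = c("sibling_swap",
                                                   "parent_generalization"),
                             multi_icon_fraction = 0.077) {
  perturbation_kind <- match.arg(perturbation_kind)
  cfg <- list(seed = as.integer(seed),
              n_primitives = as.integer(n_primitives),
              max_primitive_depth = as.integer(max_primitive_depth),
              n_concepts_a = as.integer(n_concepts_a),
              n_concepts_b = as.integer(n_concepts_b),
              poly_parent_prob = poly_parent_prob,
              manual_fraction = manual_fraction,
              crosslink_fraction = crosslink_fraction,
              discordance_rate = discordance_rate,
              perturbation_kind = perturbation_kind,
              multi_icon_fraction = multi_icon_fraction)
  probs <- c(cfg$poly_parent_prob, cfg$manual_fraction,
             cfg$crosslink_fraction, cfg$discordance_rate,
             cfg$multi_icon_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_primitives < 25L) stop("n_primitives too small (need >= 25)")
  if (cfg$max_primitive_depth < 2L) {
    stop("max_primitive_depth must be at least 2")
  }
  if (cfg$n_concepts_a < 10L || cfg$n_concepts_b < 10L) {
    stop("concept counts must be at least 10")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic sub-seed per stage/run index, kept inside 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(k)) %% 2147483629)
}

# --- hierarchy generation -------------------------------------------------

generate_hierarchy <- function(cfg) {
  comps <- default_components()
  n <- cfg$n_primitives
  # colours are small value sets; pictogram inventories dominate
  alloc <- c(central_color = max(4L, round(0.055 * n)),
             topright_color = max(4L, round(0.045 * n)),
             shape = max(6L, round(0.18 * n)),
             topright_pictogram = max(6L, round(0.175 * n)))
  alloc <- c(alloc, central_pictogram = n - sum(alloc))
  rows <- list()
  for (comp in names(alloc)) {
    k <- alloc[[comp]]
    ids <- sprintf("%s_%03d", comp, seq_len(k))
    parent <- character(k)
    depth <- integer(k)
    parent[1] <- ROOT_ID
    depth[1] <- 1L
    for (i in seq_len(k)[-1]) {
      pool <- which(depth[seq_len(i - 1L)] < cfg$max_primitive_depth)
      j <- if (length(pool) == 1L) pool else sample(pool, 1L)
      parent[i] <- ids[j]
      depth[i] <- depth[j] + 1L
    }
    rows[[comp]] <- data.frame(primitive_id = ids,
                               label = gsub("_", " ", ids),
                               component_id = comp,
                               parent_id = parent,
                               stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, c(rows, make.row.names = FALSE))
  list(components = comps,
       hierarchy = primitive_hierarchy(rows,
                                       max_depth = cfg$max_primitive_depth))
}

# Leaf-biased draw of `k` primitives of one component, never the
# component head (depth 1), so every sampled primitive has a non-root
# parent and usually siblings.
sample_primitives <- function(h, comp, k, exclude = character(0)) {
  ids <- names(h$component)[h$component == comp]
  ids <- ids[h$depth[ids] >= 2L]
  ids <- setdiff(ids, exclude)
  leaves <- ids[!(ids %in% h$parent)]
  out <- character(k)
  for (i in seq_len(k)) {
    pool <- if (length(leaves) > 0L && stats::runif(1) < 0.7) leaves else ids
    pool <- setdiff(pool, out[seq_len(i - 1L)])
    if (length(pool) == 0L) pool <- setdiff(ids, out[seq_len(i - 1L)])
    out[i] <- if (length(pool) == 1L) pool else sample(pool, 1L)
  }
  out
}

# Draw a structurally valid icon: both required slots filled, optional
# slots included with realistic probabilities.
sample_icon <- function(id, h) {
  assignment <- list(
    central_color = sample_primitives(h, "central_color", 1L),
    shape = sample_primitives(h, "shape", 1L)
  )
  if (stats::runif(1) < 0.85) {
    k <- 1L + stats::rbinom(1L, 1L, 0.25)
    assignment$central_pictogram <-
      sample_primitives(h, "central_pictogram", k)
  }
  if (stats::runif(1) < 0.3) {
    assignment$topright_color <- sample_primitives(h, "topright_color", 1L)
    assignment$topright_pictogram <-
      sample_primitives(h, "topright_pictogram", 1L)
  }
  icon(id, assignment)
}

#' Substitute one primitive of an icon
#'
#' Applies the configured perturbation while respecting component arity:
#' `sibling_swap` replaces a randomly chosen primitive by a random
#' sibling (same parent, same component); `parent_generalization`
#' replaces it by its parent. The replacement always stays in the same
#' component, so a valid icon stays valid; the perturbed icon always
#' differs from the original. If the requested kind has no eligible
#' target the other kind is tried.
#'
#' @param ic a `vcm_icon`.
#' @param h a `primitive_hierarchy`.
#' @param kind `"sibling_swap"` or `"parent_generalization"`.
#' @param new_id id for the perturbed icon.
#' @return A perturbed `vcm_icon`.
#' @export
perturb_icon <- function(ic, h, kind = c("sibling_swap",
                                         "parent_generalization"),
                         new_id = paste0(ic$id, "_pert")) {
  kind <- match.arg(kind)
  targets <- function(knd) {
    out <- list()
    for (comp in names(ic$assignment)) {
      for (p in ic$assignment[[comp]]) {
        slot <- ic$assignment[[comp]]
        repl <- if (knd == "parent_generalization") {
          par <- h$parent[[p]]
          if (!is.null(par) && par != ROOT_ID && !(par %in% slot)) par
          else character(0)
        } else {
          par <- h$parent[[p]]
          sibs <- names(h$parent)[h$parent == par &
                                    h$component == h$component[[p]]]
          setdiff(sibs, slot)
        }
        if (length(repl) > 0L) {
          out[[length(out) + 1L]] <- list(comp = comp, p = p, repl = repl)
        }
      }
    }
    out
  }
  cand <- targets(kind)
  if (length(cand) == 0L) {
    cand <- targets(setdiff(c("sibling_swap", "parent_generalization"),
                            kind))
  }
  if (length(cand) == 0L) stop("icon ", ic$id, " admits no perturbation")
  pick <- cand[[if (length(cand) == 1L) 1L else sample(length(cand), 1L)]]
  repl <- if (length(pick$repl) == 1L) pick$repl else sample(pick$repl, 1L)
  assignment <- ic$assignment
  assignment[[pick$comp]] <-
    c(setdiff(assignment[[pick$comp]], pick$p), repl)
  icon(new_id, assignment)
}

# Random concept hierarchy as parents list; node 1 is the root.
generate_concept_tree <- function(codes, max_depth, poly_parent_prob) {
  n <- length(codes)
  parents <- vector("list", n)
  depth <- integer(n)
  parents[[1]] <- character(0)
  depth[1] <- 1L
  for (i in seq_len(n)[-1]) {
    pool <- which(depth[seq_len(i - 1L)] < max_depth)
    j <- if (length(pool) == 1L) pool else sample(pool, 1L)
    parents[[i]] <- codes[j]
    depth[i] <- depth[j] + 1L
    if (poly_parent_prob > 0 && i > 2L &&
        stats::runif(1) < poly_parent_prob) {
      extra <- setdiff(seq_len(i - 1L), j)
      if (length(extra) > 0L) {
        k <- if (length(extra) == 1L) extra else sample(extra, 1L)
        parents[[i]] <- sort(c(parents[[i]], codes[k]))
        depth[i] <- max(depth[i], depth[k] + 1L)
      }
    }
  }
  list(parents = parents, depth = depth)
}

#' Generate a complete synthetic world
#'
#' Produces a primitive hierarchy, a pool of icons, a poly-hierarchic
#' terminology `a` carrying manual concept-to-icon alignments on a
#' subset of concepts (all other cross-linked concepts are descendants
#' of a manually aligned ancestor, to be filled in by
#' [inherit_icons()]), a mono-hierarchic terminology `b` whose
#' cross-linked concepts are manually aligned to a copy of the shared
#' "true" icon — perturbed with probability `discordance_rate` — and
#' cross-link identifiers connecting the two.
#'
#' @param cfg a `synthetic_config`.
#' @return List of class `synthetic_world` with elements `config`,
#'   `components`, `hierarchy`, `icons`, `term_a`, `term_b`, and
#'   `truth` (a `data.frame` of cross-linked pairs with the true icon id
#'   and a `perturbed` flag).
#' @export
generate_world <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  sub <- vapply(1:6, function(k) derive_seed(cfg$seed, k), integer(1))

  hw <- with_seed(sub[1], generate_hierarchy(cfg))
  h <- hw$hierarchy

  # --- terminology a (poly): manual anchors + inheriting chains ----------
  n_links <- min(round(cfg$crosslink_fraction *
                         min(cfg$n_concepts_a, cfg$n_concepts_b)),
                 cfg$n_concepts_a - 2L, cfg$n_concepts_b - 2L)
  n_manual_links <- round(cfg$manual_fraction * n_links)
  n_auto_links <- n_links - n_manual_links

  world_a <- with_seed(sub[2], {
    codes_a <- sprintf("A%05d", seq_len(cfg$n_concepts_a))
    n_bg <- cfg$n_concepts_a - n_auto_links
    bg_codes <- codes_a[seq_len(n_bg)]
    tree <- generate_concept_tree(bg_codes, max_depth = 11L,
                                  poly_parent_prob = cfg$poly_parent_prob)
    parents <- tree$parents
    depth <- tree$depth
    # manual anchors: scattered over the background tree (root excluded)
    n_manual_total <- min(n_bg - 1L,
                          max(n_manual_links, round(0.25 * n_bg)))
    manual_codes <- sort(sample(bg_codes[-1], n_manual_total))
    # inheriting concepts: chains of length 1-3 hanging under anchors
    chain_codes <- codes_a[seq_len(n_auto_links) + n_bg]
    chain_parent <- character(n_auto_links)
    i <- 1L
    while (i <= n_auto_links) {
      anchor <- if (length(manual_codes) == 1L) manual_codes
                else sample(manual_codes, 1L)
      len <- min(sample(1:3, 1L), n_auto_links - i + 1L)
      prev <- anchor
      for (step in seq_len(len)) {
        chain_parent[i] <- prev
        prev <- chain_codes[i]
        i <- i + 1L
      }
    }
    parents <- c(parents, as.list(chain_parent))
    list(codes = codes_a, parents = parents, manual_codes = manual_codes,
         chain_codes = chain_codes)
  })

  aside <- with_seed(sub[3], {
    icons_a <- list()
    rows <- list()
    for (i in seq_along(world_a$manual_codes)) {
      k <- 1L + (stats::runif(1) < cfg$multi_icon_fraction)
      for (j in seq_len(k)) {
        ic <- sample_icon(sprintf("IC%05d_%d", i, j), h)
        icons_a[[length(icons_a) + 1L]] <- ic
        rows[[length(rows) + 1L]] <-
          data.frame(code = world_a$manual_codes[i], icon_id = ic$id,
                     provenance = "manual", stringsAsFactors = FALSE)
      }
    }
    list(icons = icons_a, align = do.call(rbind, rows))
  })
  icons_a <- aside$icons
  manual_align_a <- aside$align

  concepts_a <- data.frame(code = world_a$codes,
                           label = paste("concept", world_a$codes),
                           stringsAsFactors = FALSE)
  concepts_a$parents <- world_a$parents
  concepts_a$cross_ids <- rep(list(character(0)), nrow(concepts_a))

  term_a <- terminology("poly_a", "poly", concepts_a, manual_align_a)
  # generator-internal inheritance run: defines the a-side truth that the
  # pipeline's own inherit_icons() call will reproduce
  term_a_inh <- inherit_icons(term_a)

  # --- cross-links and terminology b (mono) ------------------------------
  linked <- with_seed(sub[4], {
    manual_lk <- sort(sample(world_a$manual_codes, n_manual_links))
    auto_lk <- sort(sample(world_a$chain_codes, n_auto_links))
    c(manual_lk, auto_lk)
  })
  cross_ids <- sprintf("C%06d", seq_along(linked))

  world_b <- with_seed(sub[5], {
    codes_b <- sprintf("B%05d", seq_len(cfg$n_concepts_b))
    tree <- generate_concept_tree(codes_b, max_depth = 7L,
                                  poly_parent_prob = 0)
    linked_b <- sort(sample(codes_b[-1], length(linked)))
    list(codes = codes_b, parents = tree$parents, linked_b = linked_b)
  })

  # b-side icons: copy of the a-side truth, perturbed with prob delta
  bside <- with_seed(sub[6], {
    perturbed <- logical(length(linked))
    align_b <- vector("list", length(linked))
    extra_icons <- list()
    true_icon <- character(length(linked))
    all_icons <- icon_set(icons_a)
    for (i in seq_along(linked)) {
      a_icons <- aligned_icons(term_a_inh, linked[i])
      true_icon[i] <- a_icons[1]
      b_code <- world_b$linked_b[i]
      if (stats::runif(1) < cfg$discordance_rate) {
        pert <- perturb_icon(all_icons[[true_icon[i]]], h,
                             kind = cfg$perturbation_kind,
                             new_id = paste0(true_icon[i], "p", i))
        extra_icons[[length(extra_icons) + 1L]] <- pert
        perturbed[i] <- TRUE
        b_icon <- pert$id
      } else {
        b_icon <- true_icon[i]
      }
      icon_ids <- b_icon
      if (stats::runif(1) < cfg$multi_icon_fraction) {
        extra <- sample_icon(sprintf("BX%05d", i), h)
        extra_icons[[length(extra_icons) + 1L]] <- extra
        icon_ids <- c(icon_ids, extra$id)
      }
      align_b[[i]] <- data.frame(code = b_code, icon_id = icon_ids,
                                 provenance = "manual",
                                 stringsAsFactors = FALSE)
    }
    list(perturbed = perturbed, align_b = do.call(rbind, align_b),
         extra_icons = extra_icons, true_icon = true_icon)
  })

  icons <- icon_set(c(icons_a, bside$extra_icons))

  concepts_a$cross_ids[match(linked, concepts_a$code)] <-
    as.list(cross_ids)
  concepts_b <- data.frame(code = world_b$codes,
                           label = paste("concept", world_b$codes),
                           stringsAsFactors = FALSE)
  concepts_b$parents <- world_b$parents
  concepts_b$cross_ids <- rep(list(character(0)), nrow(concepts_b))
  concepts_b$cross_ids[match(world_b$linked_b, concepts_b$code)] <-
    as.list(cross_ids)

  term_a <- terminology("poly_a", "poly", concepts_a, manual_align_a,
                        icons = icons)
  term_b <- terminology("mono_b", "mono", concepts_b, bside$align_b,
                        icons = icons)

  truth <- data.frame(cross_id = cross_ids, code_a = linked,
                      code_b = world_b$linked_b,
                      true_icon = bside$true_icon,
                      perturbed = bside$perturbed,
                      stringsAsFactors = FALSE)

  structure(list(config = cfg, components = hw$components, hierarchy = h,
                 icons = icons, term_a = term_a, term_b = term_b,
                 truth = truth),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic world: ", nrow(x$hierarchy$primitives), " primitives, ",
      nrow(x$term_a$concepts), "+", nrow(x$term_b$concepts),
      " concepts, ", nrow(x$truth), " cross-linked pairs (",
      sum(x$truth$perturbed), " perturbed)\n", sep = "")
  invisible(x)
}

#' Run the full agreement pipeline on a world
#'
#' Inherits icons in the poly terminology, pairs concepts by cross id,
#' applies the single-icon filter, builds corpus probabilities from the
#' full set of alignment records, scores every retained pair with the
#' three metrics under Lin similarity, and summarises.
#'
#' @param world a `synthetic_world` (or any list with the same fields).
#' @param weighting corpus weighting mode, see
#'   [build_corpus_probabilities()].
#' @return List with `evaluations` (per-pair `data.frame`), `report`
#'   (`agreement_report`), `filter` (single-icon filter result) and
#'   `term_a` (the poly terminology after inheritance).
#' @export
evaluate_world <- function(world, weighting = "per_relation") {
  term_a <- inherit_icons(world$term_a)
  pairs <- pair_by_cross_id(term_a, world$term_b)
  pairs <- pairs_with_icons(pairs, term_a, world$term_b)
  flt <- filter_single_icon_pairs(pairs)
  probs <- build_corpus_probabilities(list(term_a, world$term_b),
                                      world$icons, world$hierarchy,
                                      weighting = weighting)
  sim <- lin_sim_fun(probs, world$hierarchy)
  evals <- evaluate_pairs(flt$retained, term_a, world$icons, sim)
  report <- summarize_agreement(evals,
                                excluded_count = flt$excluded_count)
  list(evaluations = evals, report = report, filter = flt,
       term_a = term_a)
}

#' Discordance-rate sweep
#'
#' Runs the full pipeline once per discordance rate, each run on a fresh
#' world with a per-rate derived seed, and tabulates the mean metrics.
#' Mean agreement is monotone non-increasing in the discordance rate up
#' to Monte-Carlo noise.
#'
#' @param cfg a `synthetic_config` (its `discordance_rate` is
#'   overridden per run).
#' @param rates increasing vector of discordance rates in `[0, 1]`.
#' @return `data.frame` with columns `delta`, `n_pairs`,
#'   `concordance`, `mean_dsc_crude`, `mean_dsc_semantic`, and the
#'   standard errors of the three means (`se_*`).
#' @export
sweep_discordance <- function(cfg, rates) {
  stopifnot(!is.unsorted(rates), all(rates >= 0 & rates <= 1))
  se <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- lapply(seq_along(rates), function(i) {
    cfg_i <- cfg
    cfg_i$discordance_rate <- rates[i]
    cfg_i$seed <- derive_seed(cfg$seed, 1000L + i)
    res <- evaluate_world(generate_world(cfg_i))
    e <- res$evaluations
    data.frame(delta = rates[i], n_pairs = nrow(e),
               concordance = mean(e$concordant),
               mean_dsc_crude = mean(e$dsc_crude),
               mean_dsc_semantic = mean(e$dsc_semantic),
               se_concordance = se(e$concordant),
               se_dsc_crude = se(e$dsc_crude),
               se_dsc_semantic = se(e$dsc_semantic))
  })
  do.call(rbind, rows)
}

#' Count monotonicity violations in a discordance sweep
#'
#' Each run of the sweep is an independent world, so the mean metrics
#' are monotone non-increasing in the discordance rate only up to
#' Monte-Carlo noise. An adjacent-rate increase counts as a violation
#' when it exceeds `z` combined standard errors of the two means.
#'
#' @param sweep output of [sweep_discordance()].
#' @param z noise allowance in combined standard errors (default 2).
#' @return Integer count of violations across the three metrics.
#' @export
sweep_monotonicity_violations <- function(sweep, z = 2) {
  cols <- c(concordance = "se_concordance",
            mean_dsc_crude = "se_dsc_crude",
            mean_dsc_semantic = "se_dsc_semantic")
  count <- 0L
  for (m in names(cols)) {
    s <- sweep[[cols[[m]]]]
    inc <- diff(sweep[[m]])
    tol <- z * sqrt(s[-1]^2 + s[-length(s)]^2)
    count <- count + sum(inc > tol)
  }
  count
}
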