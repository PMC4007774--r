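# Fixtures built in code, plus independent brute-force oracles used to
# cross-check the package's implementations.

worked_example_dir <- function() {
  system.file("extdata", "worked_example", package = "iconcord", mustWork = TRUE)
}

worked_example_world <- function() {
  dir <- worked_example_dir()
  icons <- read_icons(file.path(dir, "icons.tsv"))
  list(
    components = read_components(file.path(dir, "components.tsv")),
    hierarchy = read_primitives(file.path(dir, "primitives.tsv")),
    icons = icons,
    mesh_icon = icons[["icon_mesh_subacute_thyroiditis"]],
    icd_icon = icons[["icon_icd_subacute_thyroiditis"]],
    sim = fixture_sim_fun(read_sim_fixture(file.path(dir,
                                                     "sim_fixture.tsv")))
  )
}

# Four-primitive hierarchy root -> {A -> {B, C}, D}, one component.
diamondless_hierarchy <- function() {
  primitive_hierarchy(data.frame(
    primitive_id = c("A", "B", "C", "D"),
    label = c("A", "B", "C", "D"),
    component_id = "c1",
    parent_id = c("ROOT", "A", "A", "ROOT"),
    stringsAsFactors = FALSE
  ))
}

# Random small primitive hierarchy over two components.
random_small_hierarchy <- function(n = 12L, max_depth = 4L) {
  comp <- sample(c("c1", "c2"), n, replace = TRUE)
  comp[1:2] <- c("c1", "c2")
  ids <- sprintf("%s_p%02d", comp, seq_len(n))
  parent <- character(n)
  depth <- integer(n)
  for (i in seq_len(n)) {
    earlier <- which(comp[seq_len(i - 1L)] == comp[i] &
                       depth[seq_len(i - 1L)] < max_depth)
    if (length(earlier) == 0L) {
      parent[i] <- "ROOT"
      depth[i] <- 1L
    } else {
      j <- if (length(earlier) == 1L) earlier else sample(earlier, 1L)
      parent[i] <- ids[j]
      depth[i] <- depth[j] + 1L
    }
  }
  primitive_hierarchy(data.frame(primitive_id = ids, label = ids,
                                 component_id = comp, parent_id = parent,
                                 stringsAsFactors = FALSE),
                      max_depth = max_depth)
}

# Oracle: ancestor closure by walking the raw parent column.
oracle_closure <- function(h, id) {
  df <- h$primitives
  out <- id
  cur <- id
  repeat {
    par <- df$parent_id[df$primitive_id == cur]
    out <- c(out, par)
    if (par == "ROOT") break
    cur <- par
  }
  out
}

# Oracle: Lin similarity by enumerating all shared ancestors with
# base-10 logs (the ratio must be base-free).
oracle_lin <- function(p, q, probs, h) {
  shared <- intersect(oracle_closure(h, p), oracle_closure(h, q))
  denom <- log10(probs$p[[p]]) + log10(probs$p[[q]])
  if (denom == 0) return(if (identical(p, q)) 1 else 0)
  best <- -Inf
  for (a in shared) {
    best <- max(best, 2 * log10(probs$p[[a]]) / denom)
  }
  best
}

# Oracle: straight-line Dice computations over flattened sets.
oracle_dsc_crude <- function(a, b) {
  pa <- unique(unlist(a$assignment))
  pb <- unique(unlist(b$assignment))
  2 * sum(pa %in% pb) / (length(pa) + length(pb))
}

oracle_dsc_semantic <- function(a, b, sim) {
  pa <- unique(unlist(a$assignment))
  pb <- unique(unlist(b$assignment))
  num <- 0
  for (p in pa) num <- num + max(sapply(pb, function(q) sim(p, q)))
  for (q in pb) num <- num + max(sapply(pa, function(p) sim(p, q)))
  num / (length(pa) + length(pb))
}

# Random poly-hierarchic terminology with manual alignments on a random
# subset of concepts.
random_poly_terminology <- function(n = 50L, manual_frac = 0.3,
                                    max_parents = 2L) {
  codes <- sprintf("T%03d", seq_len(n))
  parents <- vector("list", n)
  parents[[1]] <- character(0)
  for (i in seq_len(n)[-1]) {
    k <- sample(seq_len(min(max_parents, i - 1L)), 1L)
    parents[[i]] <- sort(sample(codes[seq_len(i - 1L)], k))
  }
  concepts <- data.frame(code = codes, label = codes,
                         stringsAsFactors = FALSE)
  concepts$parents <- parents
  concepts$cross_ids <- rep(list(character(0)), n)
  manual <- sort(sample(codes, max(1L, round(manual_frac * n))))
  align <- do.call(rbind, lapply(manual, function(code) {
    data.frame(code = code,
               icon_id = sprintf("I%02d", sample(30L, sample(1:2, 1L))),
               provenance = "manual", stringsAsFactors = FALSE)
  }))
  terminology("rand", "poly", concepts, align)
}

# Oracle: closest manually aligned ancestors via igraph shortest paths
# on the child -> parent graph.
oracle_inherit_sources <- function(t, code) {
  manual <- unique(t$alignments$code[t$alignments$provenance == "manual"])
  if (code %in% manual) return(NULL)
  edges <- do.call(rbind, lapply(seq_len(nrow(t$concepts)), function(i) {
    p <- t$concepts$parents[[i]]
    if (length(p) == 0L) return(NULL)
    cbind(t$concepts$code[i], p)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  if (!(code %in% igraph::V(g)$name)) return(character(0))
  reach <- intersect(manual, igraph::V(g)$name)
  if (length(reach) == 0L) return(character(0))
  dm <- igraph::distances(g, v = code, to = reach, mode = "out")
  dv <- stats::setNames(dm[1, ], colnames(dm))
  dv <- dv[is.finite(dv) & dv > 0]
  if (length(dv) == 0L) return(character(0))
  sort(names(dv)[dv == min(dv)])
}
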