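# All tables are UTF-8, tab-delimited with a header row; `|` separates
# in-cell lists; tabs are forbidden in labels. Readers reject duplicate
# primary keys and name the offending line (header = line 1).

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL,
                          fileEncoding = "UTF-8")
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop(path, ": missing columns: ", paste(missing, collapse = ", "))
  }
  df
}

check_unique_key <- function(df, key_cols, path) {
  key <- do.call(paste, c(df[key_cols], sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop(path, ": duplicate key (", paste(key_cols, collapse = ", "),
         ") at line ", dup[1] + 1L)
  }
  invisible(df)
}

split_pipe <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || s == "") character(0) else sort(strsplit(s, "|",
                                                    fixed = TRUE)[[1]])
  })
}

join_pipe <- function(lst) {
  vapply(lst, paste, character(1), collapse = "|")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a component table
#'
#' Format: `component_id, name, required(0/1), multi_valued(0/1)`.
#'
#' @param path file path.
#' @return [read_components()]: a `component_table`.
#' @export
read_components <- function(path) {
  df <- read_tsv_checked(path, c("component_id", "name", "required",
                                 "multi_valued"))
  check_unique_key(df, "component_id", path)
  component_table(df$component_id, df$name,
                  required = df$required == "1",
                  multi_valued = df$multi_valued == "1")
}

#' @rdname read_components
#' @param components a `component_table`.
#' @export
write_components <- function(components, path) {
  df <- as.data.frame(components)
  df$required <- as.integer(df$required)
  df$multi_valued <- as.integer(df$multi_valued)
  write_tsv(df, path)
}

#' Read / write a primitive hierarchy table
#'
#' Format: `primitive_id, label, component_id, parent_id`; top-level
#' primitives use the reserved parent `ROOT`.
#'
#' @param path file path.
#' @param max_depth maximum depth below the root (default 6).
#' @return [read_primitives()]: a `primitive_hierarchy`.
#' @export
read_primitives <- function(path, max_depth = 6L) {
  df <- read_tsv_checked(path, c("primitive_id", "label", "component_id",
                                 "parent_id"))
  check_unique_key(df, "primitive_id", path)
  primitive_hierarchy(df, max_depth = max_depth)
}

#' @rdname read_primitives
#' @param hierarchy a `primitive_hierarchy`.
#' @export
write_primitives <- function(hierarchy, path) {
  write_tsv(hierarchy$primitives, path)
}

#' Read / write icons in long format
#'
#' Format: `icon_id, component_id, primitive_id`, one row per primitive
#' occurrence in an icon.
#'
#' @param path file path.
#' @return [read_icons()]: an `icon_set`.
#' @export
read_icons <- function(path) {
  df <- read_tsv_checked(path, c("icon_id", "component_id",
                                 "primitive_id"))
  check_unique_key(df, c("icon_id", "component_id", "primitive_id"), path)
  icons <- lapply(split(df, df$icon_id), function(rows) {
    icon(rows$icon_id[1], split(rows$primitive_id, rows$component_id))
  })
  icon_set(unname(icons))
}

#' @rdname read_icons
#' @param icons an `icon_set`.
#' @export
write_icons <- function(icons, path) {
  rows <- lapply(icons, function(ic) {
    comp <- rep(names(ic$assignment), lengths(ic$assignment))
    data.frame(icon_id = ic$id, component_id = comp,
               primitive_id = unlist(ic$assignment, use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, c(rows, make.row.names = FALSE)), path)
}

#' Read / write concept tables
#'
#' Format: `terminology_id, code, label, parents, cross_ids`; `parents`
#' and `cross_ids` are pipe-separated lists (empty for roots / unlinked
#' concepts).
#'
#' @param path file path.
#' @param terminology_id optionally keep only one terminology's rows.
#' @return [read_concepts()]: a `data.frame` with list-columns `parents`
#'   and `cross_ids`.
#' @export
read_concepts <- function(path, terminology_id = NULL) {
  df <- read_tsv_checked(path, c("terminology_id", "code", "label",
                                 "parents", "cross_ids"))
  check_unique_key(df, c("terminology_id", "code"), path)
  if (!is.null(terminology_id)) {
    df <- df[df$terminology_id == terminology_id, , drop = FALSE]
  }
  out <- data.frame(code = df$code, label = df$label,
                    stringsAsFactors = FALSE)
  out$parents <- split_pipe(df$parents)
  out$cross_ids <- split_pipe(df$cross_ids)
  rownames(out) <- NULL
  out
}

#' @rdname read_concepts
#' @param t a `terminology`.
#' @export
write_concepts <- function(t, path) {
  df <- data.frame(terminology_id = t$id, code = t$concepts$code,
                   label = t$concepts$label,
                   parents = join_pipe(t$concepts$parents),
                   cross_ids = join_pipe(t$concepts$cross_ids),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read / write alignment tables
#'
#' Format: `terminology_id, code, icon_id, provenance(manual|automatic)`.
#'
#' @param path file path.
#' @param terminology_id optionally keep only one terminology's rows.
#' @return [read_alignments()]: a `data.frame` with columns `code`,
#'   `icon_id`, `provenance`.
#' @export
read_alignments <- function(path, terminology_id = NULL) {
  df <- read_tsv_checked(path, c("terminology_id", "code", "icon_id",
                                 "provenance"))
  check_unique_key(df, c("terminology_id", "code", "icon_id"), path)
  if (!is.null(terminology_id)) {
    df <- df[df$terminology_id == terminology_id, , drop = FALSE]
  }
  data.frame(code = df$code, icon_id = df$icon_id,
             provenance = df$provenance, stringsAsFactors = FALSE)
}

#' @rdname read_alignments
#' @param t a `terminology`.
#' @export
write_alignments <- function(t, path) {
  df <- cbind(data.frame(terminology_id = t$id, stringsAsFactors = FALSE),
              t$alignments)
  write_tsv(df, path)
}

#' Read a pairwise similarity fixture table
#'
#' Format: `primitive_a, primitive_b, similarity`; the symmetric closure
#' is applied by [fixture_sim_fun()].
#'
#' @param path file path.
#' @return A `data.frame` with numeric `similarity`.
#' @export
read_sim_fixture <- function(path) {
  df <- read_tsv_checked(path, c("primitive_a", "primitive_b",
                                 "similarity"))
  check_unique_key(df, c("primitive_a", "primitive_b"), path)
  df$similarity <- as.numeric(df$similarity)
  df
}

#' Load a terminology from concept and alignment tables
#'
#' @param concepts_path,alignments_path TSV files (see
#'   [read_concepts()], [read_alignments()]); `alignments_path` may be
#'   `NULL` for an unaligned terminology.
#' @param id terminology identifier (selects rows in shared files).
#' @param hierarchy_kind `"poly"` or `"mono"`.
#' @param icons optional `icon_set` for referential checks.
#' @return A `terminology`.
#' @export
load_terminology <- function(concepts_path, alignments_path = NULL, id,
                             hierarchy_kind = c("poly", "mono"),
                             icons = NULL) {
  hierarchy_kind <- match.arg(hierarchy_kind)
  concepts <- read_concepts(concepts_path, terminology_id = id)
  if (nrow(concepts) == 0L) {
    stop(concepts_path, ": no concepts for terminology '", id, "'")
  }
  alignments <- if (is.null(alignments_path)) NULL else {
    read_alignments(alignments_path, terminology_id = id)
  }
  terminology(id, hierarchy_kind, concepts, alignments, icons = icons)
}

#' Write a synthetic world to a directory of TSV files
#'
#' Emits the same formats the loaders read: `components.tsv`,
#' `primitives.tsv`, `icons.tsv`, `concepts.tsv` and `alignments.tsv`
#' (both terminologies share the latter two files, distinguished by
#' `terminology_id`).
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_components(world$components, file.path(dir, "components.tsv"))
  write_primitives(world$hierarchy, file.path(dir, "primitives.tsv"))
  write_icons(world$icons, file.path(dir, "icons.tsv"))
  concept_rows <- function(t) {
    data.frame(terminology_id = t$id, code = t$concepts$code,
               label = t$concepts$label,
               parents = join_pipe(t$concepts$parents),
               cross_ids = join_pipe(t$concepts$cross_ids),
               stringsAsFactors = FALSE)
  }
  alignment_rows <- function(t) {
    cbind(data.frame(terminology_id = rep(t$id, nrow(t$alignments)),
                     stringsAsFactors = FALSE),
          t$alignments)
  }
  write_tsv(rbind(concept_rows(world$term_a), concept_rows(world$term_b)),
            file.path(dir, "concepts.tsv"))
  write_tsv(rbind(alignment_rows(world$term_a),
                  alignment_rows(world$term_b)),
            file.path(dir, "alignments.tsv"))
  invisible(dir)
}

# --- end-to-end run -------------------------------------------------------

#' Configuration for a full evaluation run
#'
#' Bundles and validates the input/output paths and options of
#' [run_full_evaluation()]. All input paths must exist at construction.
#'
#' @param primitives,components,icons,concepts,alignments input TSV
#'   paths (`concepts`/`alignments` hold both terminologies, keyed by
#'   `terminology_id`).
#' @param term_a_id,term_b_id terminology identifiers: `a` is the
#'   poly-hierarchic, provenance-carrying side; `b` the mono-hierarchic
#'   side.
#' @param sim_fixture optional similarity fixture TSV; when supplied it
#'   replaces the corpus-derived Lin similarity.
#' @param out_report,out_pairs optional output paths (JSON report,
#'   per-pair TSV).
#' @param weighting corpus weighting mode (see
#'   [build_corpus_probabilities()]).
#' @param max_primitive_depth depth bound for the hierarchy loader.
#' @return A list of class `run_config`.
#' @export
run_config <- function(primitives, components, icons, concepts,
                       alignments, term_a_id, term_b_id,
                       sim_fixture = NULL, out_report = NULL,
                       out_pairs = NULL, weighting = "per_relation",
                       max_primitive_depth = 6L) {
  inputs <- c(primitives, components, icons, concepts, alignments,
              sim_fixture)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0) {
    stop("input file not found: ", paste(missing, collapse = ", "))
  }
  structure(list(primitives = primitives, components = components,
                 icons = icons, concepts = concepts,
                 alignments = alignments, term_a_id = term_a_id,
                 term_b_id = term_b_id, sim_fixture = sim_fixture,
                 out_report = out_report, out_pairs = out_pairs,
                 weighting = weighting,
                 max_primitive_depth = as.integer(max_primitive_depth)),
            class = "run_config")
}

#' Run the full inter-alignment evaluation from files
#'
#' Loads the hierarchy, icons and both terminologies, inherits icons in
#' the poly-hierarchic terminology, pairs concepts by shared cross ids,
#' applies the single-icon filter, scores every retained pair with the
#' three agreement metrics (Lin similarity over the alignment corpus,
#' or a fixture table when supplied), summarises by provenance stratum,
#' and optionally writes the report (JSON) and the per-pair table
#' (TSV). Each stage logs its counts; a failing stage aborts with its
#' name and any partial outputs are removed.
#'
#' @param cfg a `run_config`.
#' @return As [evaluate_world()], invisibly.
#' @export
run_full_evaluation <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      for (p in c(cfg$out_report, cfg$out_pairs)) {
        if (!is.null(p) && file.exists(p)) unlink(p)
      }
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  world <- stage("load", {
    components <- read_components(cfg$components)
    hierarchy <- read_primitives(cfg$primitives,
                                 max_depth = cfg$max_primitive_depth)
    icons <- read_icons(cfg$icons)
    term_a <- load_terminology(cfg$concepts, cfg$alignments,
                               id = cfg$term_a_id, hierarchy_kind = "poly",
                               icons = icons)
    term_b <- load_terminology(cfg$concepts, cfg$alignments,
                               id = cfg$term_b_id, hierarchy_kind = "mono",
                               icons = icons)
    message("loaded ", nrow(term_a$concepts), " + ",
            nrow(term_b$concepts), " concepts, ", length(icons),
            " icons, ", nrow(hierarchy$primitives), " primitives")
    list(components = components, hierarchy = hierarchy, icons = icons,
         term_a = term_a, term_b = term_b)
  })
  term_a <- stage("inherit", inherit_icons(world$term_a))
  pairs <- stage("pair", {
    p <- pair_by_cross_id(term_a, world$term_b)
    message("paired ", nrow(p), " cross-linked concept pairs")
    pairs_with_icons(p, term_a, world$term_b)
  })
  flt <- stage("filter", {
    f <- filter_single_icon_pairs(pairs)
    message("retained ", nrow(f$retained), " single-icon pairs (",
            f$excluded_count, " excluded)")
    f
  })
  sim <- stage("similarity", {
    if (!is.null(cfg$sim_fixture)) {
      fixture_sim_fun(read_sim_fixture(cfg$sim_fixture))
    } else {
      probs <- build_corpus_probabilities(list(term_a, world$term_b),
                                          world$icons, world$hierarchy,
                                          weighting = cfg$weighting)
      lin_sim_fun(probs, world$hierarchy)
    }
  })
  evals <- stage("evaluate",
                 evaluate_pairs(flt$retained, term_a, world$icons, sim))
  report <- stage("summarize",
                  summarize_agreement(evals,
                                      excluded_count = flt$excluded_count))
  stage("write", {
    if (!is.null(cfg$out_pairs)) write_tsv(evals, cfg$out_pairs)
    if (!is.null(cfg$out_report)) write_report(report, cfg$out_report)
  })
  invisible(list(evaluations = evals, report = report, filter = flt,
                 term_a = term_a))
}

#' Write / read an agreement report as JSON
#'
#' The machine-readable rendering keeps full precision; the
#' human-readable rendering (the `print()` method) rounds percentages
#' to one decimal and Dice coefficients to two, listing strata as
#' Total / Manual / Automatic. `read_report(write_report(r))` returns a
#' structure equal to `r` at full precision.
#'
#' @param report an `agreement_report`.
#' @param path output / input JSON path.
#' @export
write_report <- function(report, path) {
  x <- unclass(report)
  x$strata <- lapply(x$strata, function(st) {
    for (f in c("concordance", "dsc_crude", "dsc_semantic")) {
      st[[f]] <- as.list(st[[f]])
    }
    st
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_report
#' @return [read_report()]: an `agreement_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix_ci <- function(ci) {
    ci <- unlist(ci)
    c(estimate = ci[["estimate"]], lower = ci[["lower"]],
      upper = ci[["upper"]])
  }
  x$strata <- lapply(x$strata, function(st) {
    list(n = as.integer(st$n), n_concordant = as.integer(st$n_concordant),
         concordance = fix_ci(st$concordance),
         dsc_crude = fix_ci(st$dsc_crude),
         dsc_semantic = fix_ci(st$dsc_semantic))
  })
  x$p_values <- lapply(x$p_values,
                       function(p) if (is.null(p)) NA_real_ else p)
  x$excluded_count <- as.integer(x$excluded_count)
  structure(x[c("strata", "p_values", "excluded_count")],
            class = "agreement_report")
}
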