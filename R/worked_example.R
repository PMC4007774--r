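#' Run the packaged worked example
#'
#' The package ships a minimal fixture world: one MeSH-like and one
#' ICD10-like concept sharing a cross identifier ("subacute
#' thyroiditis"), each manually aligned to a different icon, plus the
#' printed pairwise similarities (endocrine system vs thyroid 0.85,
#' disease vs inflammation 0.35) injected as a fixture table. The two
#' icons disagree: the crude Dice coefficient is 4/7 and the semantic
#' Dice coefficient 6.05/7, while binary concordance is 0.
#'
#' The fixture similarities are inputs, not outputs: the corpus that
#' produced them is not recoverable, so worked-example mode bypasses the
#' corpus-derived Lin similarity.
#'
#' @param out_report,out_pairs optional output paths, as in
#'   [run_config()].
#' @param quiet suppress stage logging (default `TRUE`).
#' @return As [run_full_evaluation()]: list with `evaluations`,
#'   `report`, `filter`, `term_a`.
#' @export
worked_example <- function(out_report = NULL, out_pairs = NULL,
                           quiet = TRUE) {
  dir <- system.file("extdata", "worked_example", package = "iconcord",
                     mustWork = TRUE)
  cfg <- run_config(
    primitives = file.path(dir, "primitives.tsv"),
    components = file.path(dir, "components.tsv"),
    icons = file.path(dir, "icons.tsv"),
    concepts = file.path(dir, "concepts.tsv"),
    alignments = file.path(dir, "alignments.tsv"),
    term_a_id = "mesh", term_b_id = "icd10",
    sim_fixture = file.path(dir, "sim_fixture.tsv"),
    out_report = out_report, out_pairs = out_pairs
  )
  if (quiet) {
    suppressMessages(run_full_evaluation(cfg))
  } else {
    run_full_evaluation(cfg)
  }
}
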