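#' Wald 95% confidence interval for a proportion
#'
#' Normal-approximation interval `p ± z * sqrt(p (1 - p) / n)`.
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return Named numeric vector `c(estimate, lower, upper)` on the
#'   proportion scale, truncated to `[0, 1]`.
#' @export
wald_ci <- function(k, n, conf = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  p <- k / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(estimate = p, lower = max(0, p - half), upper = min(1, p + half))
}

# Normal-approximation CI of a mean; degenerate (n = 1 or zero variance)
# collapses to the point estimate.
mean_ci <- function(x, conf = 0.95) {
  n <- length(x)
  m <- mean(x)
  if (n < 2L || stats::sd(x) == 0) {
    return(c(estimate = m, lower = m, upper = m))
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z * stats::sd(x) / sqrt(n)
  c(estimate = m, lower = m - half, upper = m + half)
}

#' Attach aligned icon lists to cross-terminology pairs
#'
#' @param pairs `data.frame` from [pair_by_cross_id()].
#' @param term_a,term_b the two `terminology` objects.
#' @return The pairs with list-columns `icons_a`, `icons_b` holding the
#'   icon ids aligned to each side's concept.
#' @export
pairs_with_icons <- function(pairs, term_a, term_b) {
  pairs$icons_a <- lapply(pairs$code_a, function(c) aligned_icons(term_a, c))
  pairs$icons_b <- lapply(pairs$code_b, function(c) aligned_icons(term_b, c))
  pairs
}

#' Keep only pairs where both concepts carry exactly one icon
#'
#' Comparing more than two icons at once is ill-defined, so any pair in
#' which either concept is aligned to several icons is discarded before
#' scoring.
#'
#' @param pairs `data.frame` with list-columns `icons_a`, `icons_b`
#'   (each entry a character vector with at least one icon id).
#' @return List with `retained` (pairs with scalar columns `icon_a`,
#'   `icon_b`), `excluded_count`, and `retained_fraction`
#'   (`NA` for empty input).
#' @export
filter_single_icon_pairs <- function(pairs) {
  n <- nrow(pairs)
  if (n == 0L) {
    return(list(retained = pairs, excluded_count = 0L,
                retained_fraction = NA_real_))
  }
  stopifnot(all(lengths(pairs$icons_a) >= 1L),
            all(lengths(pairs$icons_b) >= 1L))
  keep <- lengths(pairs$icons_a) == 1L & lengths(pairs$icons_b) == 1L
  retained <- pairs[keep, , drop = FALSE]
  retained$icon_a <- vapply(retained$icons_a, `[[`, character(1), 1L)
  retained$icon_b <- vapply(retained$icons_b, `[[`, character(1), 1L)
  retained$icons_a <- NULL
  retained$icons_b <- NULL
  rownames(retained) <- NULL
  list(retained = retained, excluded_count = sum(!keep),
       retained_fraction = sum(keep) / n)
}

#' Score every retained pair with the three agreement metrics
#'
#' Computes, per pair, binary concordance, the crude Dice coefficient and
#' the semantic Dice coefficient, and copies the provenance flag (manual
#' vs automatic) from the poly-hierarchic terminology's alignment record
#' for that concept and icon.
#'
#' @param retained `data.frame` with columns `code_a`, `code_b`,
#'   `icon_a`, `icon_b` (from [filter_single_icon_pairs()]).
#' @param term_a the provenance-carrying terminology (side a).
#' @param icons an `icon_set` resolving all icon ids.
#' @param sim similarity source for [dsc_semantic()].
#' @return `data.frame` of pair evaluations: codes, icon ids,
#'   `provenance`, `concordant`, `dsc_crude`, `dsc_semantic`.
#' @export
evaluate_pairs <- function(retained, term_a, icons, sim) {
  n <- nrow(retained)
  prov <- character(n)
  conc <- logical(n)
  crude <- numeric(n)
  sem <- numeric(n)
  al <- term_a$alignments
  for (i in seq_len(n)) {
    ia <- icons[[retained$icon_a[i]]]
    ib <- icons[[retained$icon_b[i]]]
    if (is.null(ia) || is.null(ib)) {
      stop("pair ", i, " references an unknown icon")
    }
    hit <- al$code == retained$code_a[i] & al$icon_id == retained$icon_a[i]
    if (!any(hit)) {
      stop("no alignment record (hence no provenance) for concept ",
           retained$code_a[i], " and icon ", retained$icon_a[i])
    }
    prov[i] <- al$provenance[which(hit)[1]]
    conc[i] <- concordant(ia, ib)
    crude[i] <- dsc_crude(ia, ib)
    sem[i] <- dsc_semantic(ia, ib, sim)
  }
  data.frame(code_a = retained$code_a, code_b = retained$code_b,
             icon_a = retained$icon_a, icon_b = retained$icon_b,
             provenance = prov, concordant = conc,
             dsc_crude = crude, dsc_semantic = sem,
             stringsAsFactors = FALSE)
}

#' Stratified agreement summary with confidence intervals and tests
#'
#' Summarises pair evaluations overall and within the manual / automatic
#' provenance strata: concordance proportion with Wald 95% CI, mean
#' crude and semantic Dice with normal-approximation 95% CIs of the
#' mean, and manual-vs-automatic comparisons — Fisher's exact test on
#' the 2x2 concordance table and two-sided Wilcoxon rank-sum tests on
#' each Dice metric. Strata with no pairs are omitted and no test is
#' run; when both strata are present but a metric is identically
#' distributed (all values tied), the p-value is reported as 1.
#'
#' @param evals `data.frame` from [evaluate_pairs()].
#' @param excluded_count number of pairs dropped by the single-icon
#'   filter (carried into the report for the sensitivity analysis).
#' @return An object of class `agreement_report`: list with `strata`
#'   (named list of per-stratum summaries), `p_values`, and
#'   `excluded_count`.
#' @export
summarize_agreement <- function(evals, excluded_count = 0L) {
  stopifnot(nrow(evals) >= 1L)
  stratum_summary <- function(e) {
    list(
      n = nrow(e),
      n_concordant = sum(e$concordant),
      concordance = wald_ci(sum(e$concordant), nrow(e)),
      dsc_crude = mean_ci(e$dsc_crude),
      dsc_semantic = mean_ci(e$dsc_semantic)
    )
  }
  strata <- list(total = stratum_summary(evals))
  for (s in c("manual", "automatic")) {
    e <- evals[evals$provenance == s, , drop = FALSE]
    if (nrow(e) > 0L) strata[[s]] <- stratum_summary(e)
  }
  p_values <- list(concordance = NA_real_, dsc_crude = NA_real_,
                   dsc_semantic = NA_real_)
  if (!is.null(strata$manual) && !is.null(strata$automatic)) {
    man <- evals[evals$provenance == "manual", , drop = FALSE]
    aut <- evals[evals$provenance == "automatic", , drop = FALSE]
    tab <- matrix(c(sum(man$concordant), sum(!man$concordant),
                    sum(aut$concordant), sum(!aut$concordant)),
                  nrow = 2)
    p_values$concordance <- stats::fisher.test(tab)$p.value
    for (metric in c("dsc_crude", "dsc_semantic")) {
      x <- man[[metric]]
      y <- aut[[metric]]
      if (length(unique(c(x, y))) == 1L) {
        p_values[[metric]] <- 1
      } else {
        p_values[[metric]] <- suppressWarnings(
          stats::wilcox.test(x, y, alternative = "two.sided")$p.value
        )
      }
    }
  }
  structure(list(strata = strata, p_values = p_values,
                 excluded_count = as.integer(excluded_count)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, digits_pct = 1, digits_dsc = 2, ...) {
  fmt_pct <- function(ci) sprintf("%.*f%% [%.*f-%.*f]",
                                  digits_pct, 100 * ci[["estimate"]],
                                  digits_pct, 100 * ci[["lower"]],
                                  digits_pct, 100 * ci[["upper"]])
  fmt_dsc <- function(ci) sprintf("%.*f [%.*f-%.*f]",
                                  digits_dsc, ci[["estimate"]],
                                  digits_dsc, ci[["lower"]],
                                  digits_dsc, ci[["upper"]])
  fmt_p <- function(p) if (is.na(p)) "-" else format.pval(p, digits = 3)
  order <- intersect(c("total", "manual", "automatic"), names(x$strata))
  cat("Inter-alignment agreement report\n")
  for (s in order) {
    st <- x$strata[[s]]
    cat(sprintf("  %-9s (n = %d): concordance %s | DSC_crude %s | DSC_semantic %s\n",
                s, st$n, fmt_pct(st$concordance), fmt_dsc(st$dsc_crude),
                fmt_dsc(st$dsc_semantic)))
  }
  missing <- setdiff(c("manual", "automatic"), names(x$strata))
  for (s in missing) cat(sprintf("  %-9s : —\n", s))
  cat(sprintf("  manual vs automatic: concordance p = %s (Fisher), DSC_crude p = %s, DSC_semantic p = %s (Wilcoxon)\n",
              fmt_p(x$p_values$concordance), fmt_p(x$p_values$dsc_crude),
              fmt_p(x$p_values$dsc_semantic)))
  cat("  excluded multi-icon pairs:", x$excluded_count, "\n")
  invisible(x)
}

#' Worst-case sensitivity to excluded multi-icon pairs
#'
#' Recomputes the stratum results under the pessimistic assumption that
#' every excluded pair was fully discordant (all three metrics scored
#' 0): the concordant count stays fixed while the denominator grows by
#' the excluded count, and the Dice means are diluted by the same
#' factor.
#'
#' @param n stratum size actually scored.
#' @param n_concordant concordant count in the stratum (recover it from
#'   a printed percentage as `round(pct * n)` if needed).
#' @param mean_dsc_crude,mean_dsc_semantic stratum means.
#' @param excluded_n number of excluded pairs assumed discordant.
#' @return Named numeric vector `c(concordance, dsc_crude,
#'   dsc_semantic)` (concordance as a proportion).
#' @export
worst_case_sensitivity <- function(n, n_concordant, mean_dsc_crude,
                                   mean_dsc_semantic, excluded_n) {
  stopifnot(excluded_n >= 0)
  total <- n + excluded_n
  if (total == 0) stop("no pairs: n + excluded_n is 0")
  c(concordance = n_concordant / total,
    dsc_crude = mean_dsc_crude * n / total,
    dsc_semantic = mean_dsc_semantic * n / total)
}
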