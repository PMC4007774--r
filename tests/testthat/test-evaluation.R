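test_that("single-icon filtering reproduces the published retention arithmetic", {
  # 1,887 cross-terminology pairs of which 281 carry a multi-icon side
  pairs <- data.frame(code_a = sprintf("m%04d", 1:1887),
                      code_b = sprintf("i%04d", 1:1887),
                      stringsAsFactors = FALSE)
  pairs$icons_a <- rep(list("I1"), 1887)
  pairs$icons_b <- rep(list("I2"), 1887)
  pairs$icons_a[1:281] <- list(c("I1", "I3"))
  flt <- filter_single_icon_pairs(pairs)
  expect_equal(nrow(flt$retained), 1606)
  expect_equal(flt$excluded_count, 281)
  expect_equal(round(100 * flt$retained_fraction, 1), 85.1)

  toy <- data.frame(code_a = letters[1:4], code_b = LETTERS[1:4],
                    stringsAsFactors = FALSE)
  toy$icons_a <- list("x", c("x", "y"), "x", "x")
  toy$icons_b <- rep(list("z"), 4)
  flt2 <- filter_single_icon_pairs(toy)
  expect_equal(nrow(flt2$retained), 3)
  expect_equal(flt2$retained$icon_a, rep("x", 3))

  all_single <- toy[-2, ]
  expect_equal(filter_single_icon_pairs(all_single)$retained_fraction, 1)
  empty <- toy[0, ]
  expect_true(is.na(filter_single_icon_pairs(empty)$retained_fraction))
})

test_that("pair scoring matches a straight-line reimplementation", {
  w <- generate_world(synthetic_config(seed = 31, n_concepts_a = 120,
                                       n_concepts_b = 120,
                                       discordance_rate = 0.5))
  term_a <- inherit_icons(w$term_a)
  pairs <- pairs_with_icons(pair_by_cross_id(term_a, w$term_b),
                            term_a, w$term_b)
  flt <- filter_single_icon_pairs(pairs)
  probs <- build_corpus_probabilities(list(term_a, w$term_b), w$icons,
                                      w$hierarchy)
  sim <- lin_sim_fun(probs, w$hierarchy)
  evals <- evaluate_pairs(flt$retained, term_a, w$icons, sim)
  expect_true(all(evals$provenance %in% c("manual", "automatic")))
  pick <- seq_len(min(20, nrow(evals)))
  for (i in pick) {
    a <- w$icons[[evals$icon_a[i]]]
    b <- w$icons[[evals$icon_b[i]]]
    expect_equal(evals$dsc_crude[i], oracle_dsc_crude(a, b))
    expect_equal(evals$dsc_semantic[i], oracle_dsc_semantic(a, b, sim))
    expect_identical(evals$concordant[i], icons_identical(a, b))
  }
})

test_that("scoring fails loudly when provenance is unavailable", {
  w <- worked_example_world()
  concepts <- data.frame(code = "m1", label = "m1",
                         stringsAsFactors = FALSE)
  concepts$parents <- list(character(0))
  concepts$cross_ids <- list("C1")
  term_a <- terminology("a", "poly", concepts)  # no alignment records
  retained <- data.frame(code_a = "m1", code_b = "i1",
                         icon_a = "icon_mesh_subacute_thyroiditis",
                         icon_b = "icon_icd_subacute_thyroiditis",
                         stringsAsFactors = FALSE)
  expect_error(evaluate_pairs(retained, term_a, w$icons, w$sim),
               "no alignment record")
})

test_that("Wald interval identifies the published confidence bounds", {
  ci <- wald_ci(392, 528)
  expect_equal(round(100 * ci[["estimate"]], 1), 74.2)
  expect_equal(round(100 * ci[["lower"]], 1), 70.5)
  expect_equal(round(100 * ci[["upper"]], 1), 78.0)
})

test_that("stratified summary behaves on degenerate and mixed inputs", {
  perfect <- data.frame(
    code_a = sprintf("a%d", 1:10), code_b = sprintf("b%d", 1:10),
    icon_a = "I", icon_b = "I",
    provenance = rep(c("manual", "automatic"), 5),
    concordant = TRUE, dsc_crude = 1, dsc_semantic = 1,
    stringsAsFactors = FALSE
  )
  rep_perfect <- summarize_agreement(perfect)
  for (s in c("total", "manual", "automatic")) {
    st <- rep_perfect$strata[[s]]
    expect_equal(st$concordance[["estimate"]], 1)
    expect_equal(st$concordance[["lower"]], 1)
    expect_equal(st$dsc_crude[["estimate"]], 1)
    expect_equal(st$dsc_semantic[["estimate"]], 1)
  }
  # identical manual and automatic distributions -> all p-values 1
  expect_equal(rep_perfect$p_values$concordance, 1)
  expect_equal(rep_perfect$p_values$dsc_crude, 1)
  expect_equal(rep_perfect$p_values$dsc_semantic, 1)

  # stratum sizes sum to the total; overall means sit between strata means
  mixed <- perfect
  mixed$concordant <- mixed$provenance == "manual"
  mixed$dsc_crude <- ifelse(mixed$provenance == "manual", 0.95, 0.80)
  mixed$dsc_semantic <- ifelse(mixed$provenance == "manual", 0.99, 0.90)
  rep_mixed <- summarize_agreement(mixed, excluded_count = 3L)
  expect_equal(rep_mixed$strata$manual$n + rep_mixed$strata$automatic$n,
               rep_mixed$strata$total$n)
  for (m in c("dsc_crude", "dsc_semantic")) {
    tot <- rep_mixed$strata$total[[m]][["estimate"]]
    expect_gte(tot, min(rep_mixed$strata$manual[[m]][["estimate"]],
                        rep_mixed$strata$automatic[[m]][["estimate"]]))
    expect_lte(tot, max(rep_mixed$strata$manual[[m]][["estimate"]],
                        rep_mixed$strata$automatic[[m]][["estimate"]]))
  }
  expect_lt(rep_mixed$p_values$concordance, 0.05)
  expect_equal(rep_mixed$excluded_count, 3L)

  # a provenance stratum with no pairs is omitted and no test runs
  manual_only <- perfect[perfect$provenance == "manual", ]
  rep_manual <- summarize_agreement(manual_only)
  expect_null(rep_manual$strata$automatic)
  expect_true(is.na(rep_manual$p_values$concordance))
})

test_that("worst-case sensitivity reproduces the published adjusted values", {
  adj <- worst_case_sensitivity(n = 528, n_concordant = round(0.742 * 528),
                                mean_dsc_crude = 0.93,
                                mean_dsc_semantic = 0.96, excluded_n = 42)
  expect_equal(round(100 * adj[["concordance"]], 1), 68.8)
  expect_equal(round(adj[["dsc_crude"]], 2), 0.86)
  expect_equal(round(adj[["dsc_semantic"]], 2), 0.89)

  same <- worst_case_sensitivity(528, 392, 0.93, 0.96, excluded_n = 0)
  expect_equal(same[["concordance"]], 392 / 528)
  expect_equal(same[["dsc_crude"]], 0.93)

  # monotone dilution in the excluded count
  grid <- seq(0, 5000, by = 250)
  vals <- sapply(grid, function(k)
    worst_case_sensitivity(528, 392, 0.93, 0.96, k))
  for (r in 1:3) expect_true(all(diff(vals[r, ]) <= 0))
  expect_lt(vals[1, length(grid)], 0.1)
  expect_error(worst_case_sensitivity(0, 0, 0, 0, 0), "no pairs")
})
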