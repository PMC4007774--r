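make_concepts <- function(codes, parents, cross_ids = NULL) {
  df <- data.frame(code = codes, label = codes, stringsAsFactors = FALSE)
  df$parents <- parents
  df$cross_ids <- if (is.null(cross_ids)) {
    rep(list(character(0)), length(codes))
  } else cross_ids
  df
}

test_that("terminology constructor enforces referential integrity", {
  chain <- make_concepts(c("A", "B", "C"),
                         list(character(0), "A", "B"))
  al <- data.frame(code = "A", icon_id = "I1", provenance = "manual",
                   stringsAsFactors = FALSE)
  t <- terminology("t", "mono", chain, al)
  expect_s3_class(t, "terminology")
  expect_equal(nrow(t$concepts), 3)

  dangling <- make_concepts(c("A", "B"), list(character(0), "Z"))
  expect_error(terminology("t", "mono", dangling), "unknown parent: Z")

  two_par <- make_concepts(c("A", "B", "C"),
                           list(character(0), character(0), c("A", "B")))
  expect_error(terminology("t", "mono", two_par), "mono-hierarchic")
  expect_s3_class(terminology("t", "poly", two_par), "terminology")

  cyc <- make_concepts(c("A", "B"), list("B", "A"))
  expect_error(terminology("t", "poly", cyc), "cycle")

  bad_al <- data.frame(code = "Z", icon_id = "I1", provenance = "manual",
                       stringsAsFactors = FALSE)
  expect_error(terminology("t", "mono", chain, bad_al),
               "unknown concept: Z")
  bad_prov <- data.frame(code = "A", icon_id = "I1",
                         provenance = "guessed", stringsAsFactors = FALSE)
  expect_error(terminology("t", "mono", chain, bad_prov),
               "invalid provenance")
  icons <- icon_set(icon("I9", list(shape = "s")))
  expect_error(terminology("t", "mono", chain, al, icons = icons),
               "unknown icon: I1")
})

test_that("closest-ancestor inheritance follows path length over all parents", {
  # child with two routes up: manual ancestor at distance 1 beats one at
  # distance 2 through the other parent
  concepts <- make_concepts(
    c("root", "mid", "near", "far", "child"),
    list(character(0), "root", "root", "root", c("near", "mid"))
  )
  al <- data.frame(code = c("near", "root"), icon_id = c("I_near", "I_root"),
                   provenance = "manual", stringsAsFactors = FALSE)
  t <- inherit_icons(terminology("t", "poly", concepts, al))
  expect_identical(aligned_icons(t, "child"), "I_near")
  expect_identical(aligned_icons(t, "child", provenance = "automatic"),
                   "I_near")

  # direct-parent cases: inherit exactly the parent's icons
  expect_identical(aligned_icons(t, "mid"), "I_root")
  expect_identical(aligned_icons(t, "far"), "I_root")

  # concepts with no manually aligned ancestor stay unaligned
  t2 <- inherit_icons(terminology(
    "t", "poly",
    make_concepts(c("a", "b"), list(character(0), "a")),
    data.frame(code = "b", icon_id = "I1", provenance = "manual",
               stringsAsFactors = FALSE)
  ))
  expect_identical(aligned_icons(t2, "a"), character(0))
})

test_that("ties between equally close manual ancestors union their icons", {
  concepts <- make_concepts(
    c("g1", "g2", "p1", "p2", "child"),
    list(character(0), character(0), "g1", "g2", c("p1", "p2"))
  )
  al <- data.frame(code = c("g1", "g2", "g2"),
                   icon_id = c("I_a", "I_b", "I_a"),
                   provenance = "manual", stringsAsFactors = FALSE)
  t <- inherit_icons(terminology("t", "poly", concepts, al))
  # both grandparents sit at distance 2; union deduplicates I_a
  expect_identical(aligned_icons(t, "child"), c("I_a", "I_b"))
})

test_that("inheritance never touches manual records and is idempotent", {
  set.seed(202)
  for (rep in 1:10) {
    t <- random_poly_terminology(n = 40)
    manual_before <- t$alignments
    t1 <- inherit_icons(t)
    kept <- t1$alignments[t1$alignments$provenance == "manual", ]
    rownames(kept) <- NULL
    expect_identical(kept, manual_before)
    t2 <- inherit_icons(t1)
    expect_equal(t1$alignments[order(t1$alignments$code,
                                     t1$alignments$icon_id), ],
                 t2$alignments[order(t2$alignments$code,
                                     t2$alignments$icon_id), ],
                 ignore_attr = TRUE)
  }
})

test_that("inheritance matches an igraph shortest-path oracle", {
  set.seed(303)
  for (rep in 1:25) {
    t <- random_poly_terminology(n = sample(20:80, 1))
    t1 <- inherit_icons(t)
    manual <- t$alignments[t$alignments$provenance == "manual", ]
    for (code in t$concepts$code) {
      sources <- oracle_inherit_sources(t, code)
      if (is.null(sources)) next  # manually aligned concept
      got <- aligned_icons(t1, code, provenance = "automatic")
      want <- if (length(sources) == 0L) character(0) else {
        sort(unique(manual$icon_id[manual$code %in% sources]))
      }
      expect_identical(got, want)
    }
  }
})

test_that("cross-id pairing is cartesian per id, deduplicated and sorted", {
  ca <- make_concepts(c("m1", "m2"), list(character(0), character(0)),
                      list("C1", "C1"))
  cb <- make_concepts(c("i1"), list(character(0)), list("C1"))
  a <- terminology("a", "poly", ca)
  b <- terminology("b", "mono", cb)
  p <- pair_by_cross_id(a, b)
  expect_equal(nrow(p), 2)
  expect_identical(p$code_a, c("m1", "m2"))

  # one id on each side -> one pair; none shared -> none
  ca1 <- make_concepts("m1", list(character(0)), list("C9"))
  expect_equal(nrow(pair_by_cross_id(terminology("a", "poly", ca1), b)), 0)
  cb1 <- make_concepts("i9", list(character(0)), list("C9"))
  expect_equal(nrow(pair_by_cross_id(terminology("a", "poly", ca1),
                                     terminology("b", "mono", cb1))), 1)

  # a pair sharing two ids still appears once
  ca2 <- make_concepts("m1", list(character(0)), list(c("C1", "C2")))
  cb2 <- make_concepts("i1", list(character(0)), list(c("C1", "C2")))
  p2 <- pair_by_cross_id(terminology("a", "poly", ca2),
                         terminology("b", "mono", cb2))
  expect_equal(nrow(p2), 1)

  # symmetric up to orientation
  pf <- pair_by_cross_id(a, b)
  pr <- pair_by_cross_id(b, a)
  expect_setequal(paste(pf$code_a, pf$code_b),
                  paste(pr$code_b, pr$code_a))
})
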