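test_that("structural validation flags every arity and reference violation", {
  w <- worked_example_world()
  expect_length(validate_icon(w$mesh_icon, w$hierarchy, w$components), 0)
  expect_length(validate_icon(w$icd_icon, w$hierarchy, w$components), 0)

  no_shape <- icon("x1", list(central_color = "current_condition"))
  v <- validate_icon(no_shape, w$hierarchy, w$components)
  expect_true(any(grepl("required component empty: shape", v)))

  ghost <- icon("x2", list(central_color = "current_condition",
                           shape = "disease",
                           central_pictogram = "no_such_primitive"))
  v <- validate_icon(ghost, w$hierarchy, w$components)
  expect_true(any(grepl("unknown primitive: no_such_primitive", v)))

  two_colors <- icon("x3", list(central_color = c("current_condition",
                                                  "disease"),
                                shape = "disease"))
  v <- validate_icon(two_colors, w$hierarchy, w$components)
  expect_true(any(grepl("single-valued component", v)))
  # "disease" sits in the shape component, not central_color
  expect_true(any(grepl("belongs to component", v)))

  alien <- icon("x4", list(central_color = "current_condition",
                           shape = "disease", halo = "disease"))
  v <- validate_icon(alien, w$hierarchy, w$components)
  expect_true(any(grepl("unknown component: halo", v)))
})

test_that("flattened primitive sets match the worked example cardinalities", {
  w <- worked_example_world()
  expect_setequal(primitives_of(w$mesh_icon),
                  c("current_condition", "disease", "endocrine_system"))
  expect_setequal(primitives_of(w$icd_icon),
                  c("current_condition", "disease", "inflammation",
                    "thyroid"))
  five <- icon("f", list(a = "p1", b = "p2", c = "p3", d = "p4", e = "p5"))
  expect_length(primitives_of(five), 5)
})

test_that("icon identity is exact per-component set equality", {
  w <- worked_example_world()
  expect_true(icons_identical(w$mesh_icon, w$mesh_icon))
  expect_false(icons_identical(w$mesh_icon, w$icd_icon))
  expect_false(icons_identical(w$icd_icon, w$mesh_icon))
  a <- icon("a", list(shape = "s1", topright_pictogram = "t1"))
  b <- icon("b", list(shape = "s1", topright_pictogram = "t2"))
  expect_false(icons_identical(a, b))
  # insertion order of slots and primitives is irrelevant
  c1 <- icon("c1", list(shape = c("s2", "s1"), central_color = "k"))
  c2 <- icon("c2", list(central_color = "k", shape = c("s1", "s2")))
  expect_true(icons_identical(c1, c2))
  # an empty slot equals an absent slot
  d1 <- icon("d1", list(shape = "s1", topright_color = character(0)))
  d2 <- icon("d2", list(shape = "s1"))
  expect_true(icons_identical(d1, d2))
})

test_that("shared ancestors behave as closure intersections", {
  w <- worked_example_world()
  expect_setequal(shared_ancestors("thyroid", "thyroid", w$hierarchy),
                  c("thyroid", "endocrine_system", "ROOT"))
  expect_true("endocrine_system" %in%
                shared_ancestors("thyroid", "endocrine_system",
                                 w$hierarchy))
  # different components share only the virtual root
  expect_identical(shared_ancestors("current_condition", "thyroid",
                                    w$hierarchy), "ROOT")
  expect_error(shared_ancestors("thyroid", "nope", w$hierarchy),
               "unknown primitive")
})

test_that("ancestor closures match a brute-force walk on random hierarchies", {
  set.seed(101)
  for (rep in 1:20) {
    h <- random_small_hierarchy(n = sample(8:20, 1))
    ids <- h$primitives$primitive_id
    for (id in ids) {
      expect_setequal(primitive_ancestors(h, id), oracle_closure(h, id))
      par <- h$parent[[id]]
      if (par != "ROOT") {
        # parent closure is nested inside the child closure (minus child)
        expect_true(all(primitive_ancestors(h, par) %in%
                          setdiff(primitive_ancestors(h, id), id)))
      }
    }
    pairs <- expand.grid(p = ids, q = ids, stringsAsFactors = FALSE)
    pick <- pairs[sample(nrow(pairs), 15), ]
    for (k in seq_len(nrow(pick))) {
      p <- pick$p[k]; q <- pick$q[k]
      expect_setequal(shared_ancestors(p, q, h),
                      intersect(oracle_closure(h, p),
                                oracle_closure(h, q)))
      expect_setequal(shared_ancestors(p, q, h),
                      shared_ancestors(q, p, h))
    }
  }
})

test_that("hierarchy constructor rejects malformed input", {
  df <- data.frame(primitive_id = c("a", "b"), label = c("a", "b"),
                   component_id = "c1", parent_id = c("b", "a"),
                   stringsAsFactors = FALSE)
  expect_error(primitive_hierarchy(df), "cycle")
  df2 <- data.frame(primitive_id = "a", label = "a", component_id = "c1",
                    parent_id = "missing", stringsAsFactors = FALSE)
  expect_error(primitive_hierarchy(df2), "unknown parent")
  deep <- data.frame(primitive_id = paste0("p", 1:8),
                     label = paste0("p", 1:8), component_id = "c1",
                     parent_id = c("ROOT", paste0("p", 1:7)),
                     stringsAsFactors = FALSE)
  expect_error(primitive_hierarchy(deep, max_depth = 6), "deeper")
  cross <- data.frame(primitive_id = c("a", "b"), label = c("a", "b"),
                      component_id = c("c1", "c2"),
                      parent_id = c("ROOT", "a"), stringsAsFactors = FALSE)
  expect_error(primitive_hierarchy(cross), "different component")
})

test_that("every icon of an unperturbed synthetic world validates", {
  w <- generate_world(synthetic_config(seed = 11, n_concepts_a = 120,
                                       n_concepts_b = 120,
                                       discordance_rate = 0))
  for (ic in w$icons) {
    expect_length(validate_icon(ic, w$hierarchy, w$components), 0)
  }
})
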