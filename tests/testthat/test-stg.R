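# STG construction, attractor identification and basins.

test_that("state spaces have the expected size", {
  m <- hpa_resting_model()
  for (scheme in c("synchronous", "asynchronous"))
    expect_equal(nrow(build_stg(m, scheme)$states), 36L)
  # the priority graph enumerates extended states but covers 36 level states
  stg_p <- build_stg(m, "priority")
  expect_equal(length(unique(state_label(stg_p$x_space))), 36L)
  expect_equal(length(stg_p$initial), 36L)
  m1 <- one_node_positive_loop()
  expect_equal(nrow(build_stg(m1, "asynchronous")$states), 2L)
  expect_error(build_stg(m, "asynchronous", max_states = 10), "max_states")
})

test_that("attractor detection matches the reachability oracle on random digraphs", {
  set.seed(2024)
  for (g in 1:110) {
    n <- sample(c(3:30, 200), 1)
    edges <- lapply(seq_len(n), function(v) {
      k <- stats::rbinom(1, 3, 0.5)
      if (k == 0) integer() else sample.int(n, k)
    })
    stg <- structure(list(states = matrix(seq_len(n), ncol = 1),
                          edges = edges, scheme = "asynchronous",
                          extended = FALSE, initial = seq_len(n)),
                     class = "mv_stg")
    got <- find_attractors(stg)
    want <- oracle_attractors(edges)
    expect_equal(length(got), length(want))
    sets <- lapply(got, function(a) sort(a$vertices))
    ord <- order(vapply(sets, min, 1L))
    expect_identical(sets[ord], lapply(want, `[[`, "vertices"))
    expect_identical(vapply(got, `[[`, "", "kind")[ord],
                     vapply(want, `[[`, "", "kind"))
  }
})

test_that("attractors of random models agree with the oracle and with igraph", {
  for (seed in 1:40) {
    m <- random_model(n_nodes = 3, max_level = 2, edge_density = 0.55,
                      seed = seed)
    stg <- build_stg(m, "asynchronous", inputs = hpa_inputs0(m))
    got <- find_attractors(stg)
    want <- oracle_attractors(stg$edges)
    sets <- lapply(got, function(a) sort(a$vertices))
    expect_identical(sets[order(vapply(sets, min, 1L))],
                     lapply(want, `[[`, "vertices"))
  }
  # cross-check the SCC partition itself against igraph on one model
  m <- random_model(4, 2, 0.5, seed = 123)
  stg <- build_stg(m, "asynchronous", inputs = hpa_inputs0(m))
  el <- do.call(rbind, lapply(seq_along(stg$edges), function(v)
    if (length(stg$edges[[v]])) cbind(v, stg$edges[[v]])))
  g <- igraph::graph_from_edgelist(el, directed = TRUE)
  g <- igraph::add_vertices(g, max(0, nrow(stg$states) - igraph::vcount(g)))
  memb <- igraph::components(g, mode = "strong")$membership
  ours <- mvlogic:::tarjan_scc(stg$edges)
  expect_equal(length(unique(memb)), length(unique(ours)))
  # same partition: equal co-membership relation
  expect_true(all(outer(memb, memb, "==") == outer(ours, ours, "==")))
})

test_that("HPA attractor counts per scheme match the published reports", {
  m <- hpa_resting_model()
  att_a <- find_attractors(build_stg(m, "asynchronous"))
  expect_length(att_a, 2L)
  att_s <- find_attractors(build_stg(m, "synchronous"))
  expect_length(att_s, 4L)
  expect_true(all(vapply(att_s, `[[`, "", "kind") == "cyclic"))
  att_p <- find_attractors(build_stg(m, "priority"))
  expect_length(att_p, 2L)
})

test_that("priority attractors project to the split-range cycles", {
  m <- hpa_resting_model()
  att <- find_attractors(build_stg(m, "priority"))
  cort <- lapply(att, function(a) sort(unique(a$states[, "CORT"])))
  r <- lapply(att, function(a) sort(unique(a$states[, "R"])))
  path <- which(vapply(r, function(x) identical(x, 2L), TRUE))
  expect_length(path, 1L)
  expect_equal(cort[[path]], c(0L, 1L))       # low-range CORT, R saturated
  expect_equal(cort[[3L - path]], c(1L, 2L))  # high-range CORT
  expect_equal(r[[3L - path]], c(0L, 1L))     # with R oscillating low/mid
  # a stationary extended state projects to a stationary level state
  mh <- hpa_stress_model("heightened")
  att_h <- find_attractors(build_stg(mh, "priority", inputs = list(Stress = 1L)))
  expect_true(all(vapply(att_h, `[[`, "", "kind") == "stationary"))
  expect_true(all(vapply(att_h, function(a) nrow(a$states), 1L) == 1L))
})

test_that("basins cover the space and respect attractor membership", {
  m <- hpa_resting_model()
  for (scheme in c("asynchronous", "priority")) {
    stg <- build_stg(m, scheme)
    att <- find_attractors(stg)
    bas <- compute_basins(stg, att)
    expect_equal(nrow(bas), 36L)
    expect_true(all(lengths(bas$reachable) >= 1L))
    # attractor states reach exactly their own attractor
    for (a in att) {
      labs <- state_label(a$states)
      expect_true(all(bas$basin[bas$label %in% labs] == a$id))
    }
    # the two regimes are fully separated: every state is exclusive
    expect_false(any(is.na(bas$basin)))
  }
})

test_that("no transition edge connects the two resting regimes", {
  m <- hpa_resting_model()
  stg <- build_stg(m, "priority")
  att <- find_attractors(stg)
  bas <- compute_basins(stg, att)
  vert_reach <- attr(bas, "vertex_reach")
  # vertex-level basin labels (every vertex reaches exactly one attractor)
  expect_true(all(rowSums(vert_reach) == 1L))
  vlab <- max.col(vert_reach)
  for (v in seq_along(stg$edges))
    for (w in stg$edges[[v]])
      expect_equal(vlab[w], vlab[v])
})

test_that("attractor state sets are invariant and pairwise disjoint", {
  for (seed in 1:8) {
    m <- random_model(3, 2, 0.6, seed = seed)
    stg <- build_stg(m, "asynchronous", inputs = hpa_inputs0(m))
    att <- find_attractors(stg)
    all_v <- unlist(lapply(att, `[[`, "vertices"))
    expect_equal(anyDuplicated(all_v), 0L)
    for (a in att)
      for (v in a$vertices)
        expect_true(all(stg$edges[[v]] %in% a$vertices))
  }
})
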