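# Tendency function, the three update schemes and the memory rules.

test_that("tendency moves one step toward the image, never a jump", {
  expect_equal(tendency(c(0L, 1L, 2L), c(2L, 1L, 0L)), c(1L, 1L, 1L))
  expect_equal(tendency(c(0L, 2L), c(0L, 2L)), c(0L, 2L))
})

test_that("synchronous update is deterministic with out-degree one", {
  m <- hpa_resting_model()
  stg <- build_stg(m, "synchronous")
  expect_true(all(lengths(stg$edges) == 1L))
  expect_equal(sum(lengths(stg$edges)), nrow(stg$states))  # |E| = |V|
  # [0000] is not fixed: CORT=0 drives CRH up and R=0 disinhibits ACTH
  fp <- successors_synchronous(m, c(CRH = 0, ACTH = 0, CORT = 0, R = 0))
  expect_equal(unname(fp), c(1L, 1L, 0L, 0L))
  # trajectories are seed-independent
  t1 <- simulate_trajectory(m, c(0, 0, 0, 0), "synchronous", n_steps = 10)
  t2 <- simulate_trajectory(m, c(0, 0, 0, 0), "synchronous", n_steps = 10)
  expect_identical(t1, t2)
})

test_that("two-node negative loop cycles with period four synchronously", {
  m <- two_node_negative_loop()
  traj <- simulate_trajectory(m, c(A = 0, B = 0), "synchronous", n_steps = 4)
  expect_equal(state_label(traj),
               c("[00]", "[10]", "[11]", "[01]", "[00]"))
})

test_that("asynchronous successors are one per off-image node", {
  m <- hpa_resting_model()
  S <- enumerate_states(m, NULL)
  for (r in seq_len(nrow(S))) {
    s <- stats::setNames(S[r, ], colnames(S))
    y <- state_image(m, s)
    k <- sum(tendency(s, y) != s)
    succ <- successors_asynchronous(m, s)
    expect_length(succ, k)
    for (s2 in succ) expect_equal(sum(abs(s2 - s)), 1L)
  }
  # |E| <= n * m^n for the asynchronous graph
  stg <- build_stg(m, "asynchronous")
  expect_lte(sum(lengths(stg$edges)), 4L * nrow(stg$states))
})

test_that("memory update implements the three-case rule", {
  m <- hpa_resting_model()
  d <- m$delays
  s <- c(CRH = 0L, ACTH = 0L, CORT = 0L, R = 0L)
  ext <- extended_state(m, s)
  y <- state_image(m, s)
  # CRH just updated (level changed): its memory resets to d
  x_next <- s; x_next["CRH"] <- 1L
  m2 <- update_memory(ext, y, x_next, d)
  expect_equal(unname(m2["CRH"]), unname(d["CRH"]))
  # nodes with d = 1 are pinned at 1 whatever the case
  expect_true(all(m2[c("ACTH", "R")] == 1L))
  # CORT (d = 4) under a persistent unchanged command counts down 4,3,2,1
  ext$y_prev <- y   # image unchanged from previous iteration
  seen <- integer()
  for (k in 1:3) {
    mm <- update_memory(ext, y, ext$x, d)   # no level change anywhere
    seen <- c(seen, mm[["CORT"]])
    ext$m <- mm
  }
  expect_equal(seen, c(3L, 2L, 1L))
  # image change with unchanged level replenishes memory (F1 and F2)
  ext$m[["CORT"]] <- 2L
  y_new <- y; y_new[["CORT"]] <- y[["CORT"]] + 1L
  mm <- update_memory(ext, y_new, ext$x, d)
  expect_equal(mm[["CORT"]], 3L)
})

test_that("eligibility is the minimum-residual-memory rule", {
  m <- hpa_resting_model()
  ext <- extended_state(m, c(CRH = 0, ACTH = 0, CORT = 0, R = 0))
  # start memories are the delays (1,1,4,1): CORT is not eligible
  expect_setequal(eligible_nodes(m, ext), c("CRH", "ACTH", "R"))
  ext$m[] <- 2L
  expect_setequal(eligible_nodes(m, ext), c("CRH", "ACTH", "CORT", "R"))
  m1 <- one_node_positive_loop()
  expect_equal(eligible_nodes(m1, extended_state(m1, c(A = 0))), "A")
})

test_that("priority successors change one level and carry updated memory", {
  m <- hpa_resting_model()
  ext <- extended_state(m, c(CRH = 0, ACTH = 0, CORT = 0, R = 0))
  succ <- successors_priority(m, ext)
  # CRH and ACTH are the off-image eligible fast nodes at [0000]
  expect_length(succ, 2L)
  expect_setequal(vapply(succ, function(e) state_label(e$x), ""),
                  c("[1000]", "[0100]"))
  for (e in succ) {
    expect_equal(sum(abs(e$x - ext$x)), 1L)
    expect_false(is.null(e$y_prev))
    expect_true(all(e$m[c("CRH", "ACTH", "R")] == 1L))
  }
  # stationary extended states produce no successors
  mh <- hpa_stress_model("heightened")
  ext2 <- extended_state(mh, c(CRH = 0, ACTH = 0, CORT = 0, R = 2, Stress = 1))
  expect_length(successors_priority(mh, ext2), 0L)
})

test_that("every transition moves a single node by exactly one level", {
  for (seed in 1:6) {
    m <- random_model(n_nodes = 3, max_level = 2, edge_density = 0.6,
                      seed = seed)
    ins <- hpa_inputs0(m)
    for (scheme in c("asynchronous", "priority")) {
      stg <- build_stg(m, scheme, inputs = ins)
      for (v in seq_along(stg$edges)) for (w in stg$edges[[v]]) {
        delta <- sum(abs(stg$states[w, ] - stg$states[v, ]))
        expect_lte(delta, 1L)  # 0 only for memory-advancing idle steps
      }
    }
    stg_s <- build_stg(m, "synchronous", inputs = ins)
    for (v in seq_along(stg_s$edges))
      expect_true(all(abs(stg_s$states[stg_s$edges[[v]], ] -
                          stg_s$states[v, ]) <= 1L))
  }
})

test_that("priority transitions are a subset of asynchronous transitions", {
  models <- c(list(hpa_resting_model()),
              lapply(1:6, function(s) random_model(3, 2, 0.6, seed = s)))
  for (m in models) {
    ins <- hpa_inputs0(m)
    pri <- transition_pairs(build_stg(m, "priority", inputs = ins))
    asy <- transition_pairs(build_stg(m, "asynchronous", inputs = ins))
    expect_true(all(pri %in% asy))
  }
})

test_that("seeded trajectories are reproducible and stay inside attractors", {
  m <- hpa_resting_model()
  t1 <- simulate_trajectory(m, c(0, 0, 0, 0), "asynchronous", 30, seed = 11)
  t2 <- simulate_trajectory(m, c(0, 0, 0, 0), "asynchronous", 30, seed = 11)
  expect_identical(t1, t2)
  t3 <- simulate_trajectory(m, c(0, 0, 0, 0), "priority", 30, seed = 4)
  expect_identical(t3,
    simulate_trajectory(m, c(0, 0, 0, 0), "priority", 30, seed = 4))
  # once a trajectory enters an attractor's state set it never leaves
  stg <- build_stg(m, "asynchronous")
  att <- find_attractors(stg)
  for (a in att) {
    labs <- state_label(a$states)
    tr <- simulate_trajectory(m, a$states[1, ], "asynchronous", 60, seed = 5)
    expect_true(all(state_label(tr) %in% labs))
  }
})
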