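# Circuit enumeration/functionality and the K-space tuning workflow.

test_that("circuit enumeration matches the brute-force oracle", {
  # HPA topology: the two negative loops and the positive self-loop
  m <- hpa_resting_model()
  circ <- enumerate_circuits(m)
  expect_setequal(vapply(circ, circuit_key, ""), oracle_cycles(m$network))
  parities <- stats::setNames(vapply(circ, `[[`, "", "parity"),
                              vapply(circ, circuit_key, ""))
  expect_equal(unname(parities["ACTH>CORT>CRH"]), "-")
  expect_equal(unname(parities["ACTH>CORT>R"]), "-")
  expect_equal(unname(parities["R"]), "+")
  # random graphs against the oracle
  for (seed in 1:10) {
    m2 <- random_model(n_nodes = 4, max_level = 1, edge_density = 0.4,
                       seed = seed)
    circ2 <- enumerate_circuits(m2)
    expect_setequal(vapply(circ2, circuit_key, ""), oracle_cycles(m2$network))
    # parity arithmetic: (-1)^(number of inhibitions)
    for (ci in circ2)
      expect_equal(ci$parity, if (sum(ci$edges$sign == "-") %% 2) "-" else "+")
  }
  # acyclic graph
  net <- logical_network(
    data.frame(name = c("A", "B"), max_level = c(1, 1)),
    data.frame(source = "A", target = "B", sign = "+", threshold = 1))
  expect_length(enumerate_circuits(net), 0L)
  # double-negative two-node loop has positive parity
  net2 <- logical_network(
    data.frame(name = c("A", "B"), max_level = c(1, 1)),
    data.frame(source = c("A", "B"), target = c("B", "A"),
               sign = c("-", "-"), threshold = c(1, 1)))
  expect_equal(enumerate_circuits(net2)[[1]]$parity, "+")
})

test_that("circuit functionality discriminates the published K table", {
  m <- hpa_resting_model()
  circ <- enumerate_circuits(m)
  # all three circuits are functional under the published parameters
  expect_true(all(vapply(circ, function(ci) circuit_functional(m, ci), TRUE)))
  # a constant (all-zero) image supports no functional circuit
  z <- m
  z$parameters <- lapply(z$parameters, function(k) { k[] <- 0L; k })
  expect_false(any(vapply(circ, function(ci) circuit_functional(z, ci), TRUE)))
})

test_that("a functional positive self-loop yields two stable fixed points", {
  m <- one_node_positive_loop()
  ci <- enumerate_circuits(m)[[1]]
  expect_equal(ci$parity, "+")
  expect_true(circuit_functional(m, ci))
  att <- find_attractors(build_stg(m, "asynchronous"))
  expect_length(att, 2L)
  expect_true(all(vapply(att, `[[`, "", "kind") == "stationary"))
  expect_setequal(unlist(lapply(att, function(a) state_label(a$states))),
                  c("[0]", "[1]"))
})

test_that("parameter spaces enumerate the exact slot products", {
  m <- hpa_resting_model()
  # 2 binary CRH slots, 4 binary ACTH, 2 ternary CORT, 4 ternary R
  expect_equal(parameter_space(m)$count, 4 * 16 * 9 * 81)
  expect_equal(parameter_space(m)$count, 46656)
  one <- parameter_space(m, data.frame(node = "CRH", context = "CORT"))
  expect_equal(one$count, 2)
  # deterministic order and coverage: every candidate appears exactly once
  sp <- parameter_space(m, data.frame(node = c("CORT", "CORT"),
                                      context = c("", "ACTH")))
  expect_equal(sp$count, 9)
  seen <- vapply(seq_len(sp$count), function(i)
    paste(sp$get(i)$CORT, collapse = ","), "")
  expect_equal(anyDuplicated(seen), 0L)
  expect_length(seen, 9L)
})

test_that("tuning recovers the published CORT parameters in its slice", {
  m <- hpa_resting_model()
  res <- tune_parameters(m, "bistable_cyclic", scheme = "priority",
                         slots = data.frame(node = c("CORT", "CORT"),
                                            context = c("", "ACTH")))
  expect_equal(nrow(res), 9L)
  sp <- attr(res, "space")
  sat <- which(res$satisfied)
  k_sat <- lapply(sat, function(i) sp$get(i)$CORT)
  # the published assignment K{}=0, K{ACTH}=2 is among the feasible set
  expect_true(any(vapply(k_sat, function(k)
    k[[match("", names(k))]] == 0L && k[[match("ACTH", names(k))]] == 2L, TRUE)))
  # an unsatisfiable requirement has an empty feasible set
  res99 <- tune_parameters(m, function(att) length(att) == 99,
                           scheme = "priority",
                           slots = data.frame(node = "CRH", context = "CORT"))
  expect_false(any(res99$satisfied))
})

test_that("candidates lacking functional circuits never beat the prefilter", {
  m <- hpa_resting_model()
  space <- parameter_space(m)
  set.seed(77)
  idx <- sample.int(space$count, 150)
  circuits <- enumerate_circuits(m$network)
  for (i in idx) {
    cand <- m
    cand$parameters <- space$get(i)
    pp <- lapply(circuits, function(ci) circuit_parities(cand, ci))
    has_neg <- any(vapply(pp, function(p) "-" %in% p, TRUE))
    has_pos <- any(vapply(pp, function(p) "+" %in% p, TRUE))
    att <- find_attractors(build_stg(cand, "asynchronous"))
    kinds <- vapply(att, `[[`, "", "kind")
    if (!has_neg)
      expect_equal(sum(kinds == "cyclic"), 0L,
                   label = sprintf("candidate %d (no functional negative loop)", i))
    if (!has_pos)
      expect_lte(length(att), 1L)
  }
})

test_that("prefiltered tuning equals unfiltered tuning on a slice", {
  m <- hpa_resting_model()
  slots <- data.frame(node = c("R", "R"), context = c("R", "CORT,R"))
  with_f <- tune_parameters(m, "bistable_cyclic", scheme = "asynchronous",
                            slots = slots, prefilter = TRUE)
  without <- tune_parameters(m, "bistable_cyclic", scheme = "asynchronous",
                             slots = slots, prefilter = FALSE)
  expect_equal(with_f$satisfied, without$satisfied)
})

test_that("stress-input calibration reproduces the published census", {
  cal <- calibrate_input(hpa_resting_model(), "Stress", scheme = "priority",
                         target = "CRH")
  expect_equal(nrow(cal$table), 16L)
  census <- table(two_cyclic = cal$table$n_cyclic == 2,
                  stat_only = cal$table$n_cyclic == 0)
  expect_equal(sum(cal$table$n_cyclic == 2), 4L)
  expect_equal(sum(cal$table$n_cyclic == 1 & cal$table$n_stationary >= 1), 4L)
  expect_equal(sum(cal$table$n_cyclic == 0), 8L)
  expect_equal(sum(cal$table$rest_compatible), 4L)
  expect_length(cal$retained, 2L)
  stat_all <- unlist(strsplit(cal$table$stationary[cal$table$retained], " "))
  expect_true(all(c("[0002]", "[1122]") %in% stat_all))
  expect_setequal(names(cal$retained_params), c("normal", "heightened"))
})
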