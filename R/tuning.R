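#' Enumerate elementary feedback circuits with parity
#'
#' Finds all simple directed cycles of the regulatory graph. The parity of a
#' circuit is the product of its interaction signs: negative circuits (odd
#' number of inhibitions) are required for sustained oscillation, positive
#' circuits for multistability.
#'
#' @param network an `mv_network` (or `mv_model`).
#' @return list of circuits; each a list with `nodes` (in cycle order,
#'   starting from the smallest-index node), `edges` (data frame of the
#'   interactions traversed, row k being the edge from `nodes[k]` to the next
#'   node) and `parity` (`"+"` or `"-"`).
#' @export
enumerate_circuits <- function(network) {
  net <- if (inherits(network, "mv_network")) network else network$network
  nm <- net$nodes$name
  n <- length(nm)
  adj <- lapply(nm, function(v)
    match(net$interactions$target[net$interactions$source == v], nm))
  circuits <- list()
  # DFS restricted to nodes >= root yields each cycle once, rooted at its
  # smallest node
  path <- integer(0)
  visit <- function(v, root) {
    path <<- c(path, v)
    for (w in adj[[v]]) {
      if (w == root) {
        circuits[[length(circuits) + 1L]] <<- path
      } else if (w > root && !(w %in% path)) {
        visit(w, root)
      }
    }
    path <<- path[-length(path)]
  }
  for (root in seq_len(n)) visit(root, root)
  lapply(circuits, function(idx) {
    nodes <- nm[idx]
    nxt <- c(nodes[-1], nodes[1])
    rows <- mapply(function(s, t)
      which(net$interactions$source == s & net$interactions$target == t),
      nodes, nxt)
    edges <- net$interactions[rows, , drop = FALSE]
    rownames(edges) <- NULL
    parity <- if (sum(edges$sign == "-") %% 2 == 0) "+" else "-"
    list(nodes = nodes, edges = edges, parity = parity)
  })
}

#' Test whether a feedback circuit is functional under a parameterization
#'
#' A circuit edge `j -> i` is functional when some context (an activity
#' assignment of i's other regulators) lets the level of `j`, crossing its
#' threshold, switch the image of `i` across `theta_out(i)`, the threshold of
#' the circuit edge leaving `i`. In the generalized formalism the K values
#' decide the *realized* sign of that switch: with `K_high` the image in the
#' high-`j` context and `K_low` in the low-`j` context, the edge acts
#' positively when `K_high >= theta_out > K_low` and negatively when
#' `K_low >= theta_out > K_high` — regardless of the nominal graph sign,
#' which only fixes which context is the high one. A circuit is functional
#' when every edge is functional in some direction; the parities it can
#' realize are the products of its edges' realizable directions
#' ([circuit_parities()]). Contexts are enumerated exhaustively and
#' independently per circuit node; on binary networks with sign-consistent
#' K tables this reduces to the classical circuit-characteristic condition.
#'
#' @param model an `mv_model`.
#' @param circuit one element of [enumerate_circuits()].
#' @return `TRUE` if every circuit edge has a witnessing context.
#' @export
circuit_functional <- function(model, circuit) {
  length(circuit_parities(model, circuit)) > 0L
}

#' Realizable parities of a feedback circuit
#'
#' @inheritParams circuit_functional
#' @return character vector: subset of `c("+", "-")`, the circuit parities
#'   realizable under the model's K values (empty when some edge is not
#'   functional at all). A negative realizable parity licenses sustained
#'   oscillation, a positive one multistability.
#' @export
circuit_parities <- function(model, circuit) {
  net <- model$network
  nodes <- circuit$nodes
  k_cyc <- length(nodes)
  edge_signs <- vector("list", k_cyc)
  for (p in seq_len(k_cyc)) {
    i <- nodes[p]
    pred <- if (p == 1L) k_cyc else p - 1L
    j <- nodes[pred]                               # circuit predecessor of i
    sign_j <- circuit$edges$sign[pred]             # nominal sign of j -> i
    theta_out <- circuit$edges$threshold[p]        # edge i -> next
    kt <- model$parameters[[i]]
    others <- setdiff(net$regulators[[i]], j)
    dirs <- integer(0)
    for (ctx in all_subsets(others)) {
      k_in <- kt[[match(context_key(c(ctx, j)), names(kt))]]   # j's context active
      k_out <- kt[[match(context_key(ctx), names(kt))]]
      # the interaction context is active when x_j is high for activators and
      # low for inhibitors
      k_high <- if (sign_j == "+") k_in else k_out
      k_low <- if (sign_j == "+") k_out else k_in
      if (k_high >= theta_out && k_low < theta_out) dirs <- union(dirs, 1L)
      if (k_low >= theta_out && k_high < theta_out) dirs <- union(dirs, -1L)
    }
    if (!length(dirs)) return(character(0))
    edge_signs[[p]] <- dirs
  }
  prods <- Reduce(function(acc, d) unique(as.vector(outer(acc, d))),
                  edge_signs, 1L)
  sort(c("-", "+")[match(prods, c(-1L, 1L))])
}

#' Deterministic enumeration of a logical parameter space
#'
#' Describes the Cartesian product of K values over a set of free slots.
#' Candidates are indexed `1..count` in mixed-radix order (the last slot
#' varies fastest), so enumeration is deterministic and restartable.
#'
#' @param model an `mv_model` providing the base parameters (fixed slots keep
#'   their base value).
#' @param slots data frame with columns `node` and `context` designating the
#'   free (node, context-key) entries; `NULL` (default) frees every entry of
#'   every non-input node. Each slot ranges over `0..max_level(node)`.
#' @return list with `count`, `slots`, and `get(i)` returning the i-th full
#'   parameter list.
#' @export
parameter_space <- function(model, slots = NULL) {
  net <- model$network
  if (is.null(slots)) {
    non_input <- net$nodes$name[!net$nodes$is_input]
    slots <- do.call(rbind, lapply(non_input, function(v)
      data.frame(node = v,
                 context = vapply(all_subsets(net$regulators[[v]]), context_key, ""),
                 stringsAsFactors = FALSE)))
  }
  slots <- as.data.frame(slots, stringsAsFactors = FALSE)
  rho <- net$nodes$max_level[match(slots$node, net$nodes$name)]
  radix <- rho + 1L
  count <- prod(radix)
  base <- model$parameters
  k_slots <- nrow(slots)
  get <- function(i) {
    stopifnot(i >= 1, i <= count)
    rem <- i - 1
    vals <- integer(k_slots)
    for (s in rev(seq_len(k_slots))) {
      vals[s] <- rem %% radix[s]
      rem <- rem %/% radix[s]
    }
    pars <- base
    for (s in seq_len(k_slots)) {
      v <- slots$node[s]
      pos <- match(slots$context[s], names(pars[[v]]))
      pars[[v]][pos] <- vals[s]
    }
    pars
  }
  list(count = count, slots = slots, radix = radix, get = get)
}

# attractor census of one candidate parameterization
attractor_census <- function(model, pars, scheme, inputs) {
  cand <- model
  cand$parameters <- pars
  att <- find_attractors(build_stg(cand, scheme, inputs = inputs))
  kinds <- vapply(att, `[[`, "", "kind")
  list(attractors = att,
       n_cyclic = sum(kinds == "cyclic"),
       n_stationary = sum(kinds == "stationary"))
}

#' Exhaustive K-space search for a qualitative behavior
#'
#' Enumerates a parameter space, optionally prefilters candidates by feedback
#' circuit functionality (a candidate without a functional negative circuit
#' cannot oscillate; without a functional positive circuit it cannot be
#' multistable), and evaluates a behavior constraint on the attractor report
#' of each surviving candidate.
#'
#' @param model base `mv_model`.
#' @param constraint either the string `"bistable_cyclic"` (exactly two
#'   cyclic attractors, the built-in target behavior) or a predicate
#'   `function(attractors)` returning `TRUE`/`FALSE`.
#' @param scheme update scheme for the attractor analysis.
#' @param inputs input assignment (if the network has inputs).
#' @param slots free slots as in [parameter_space()].
#' @param prefilter apply the circuit-functionality prefilter (only for the
#'   built-in constraint, whose requirements are known).
#' @param max_candidates refuse larger enumerations.
#' @return An object of class `mv_tuning`: data frame with one row per
#'   candidate (`index`, `functional_negative`, `functional_positive`,
#'   `n_cyclic`, `n_stationary`, `satisfied`), with the space as attribute
#'   `"space"`. For prefiltered-out candidates the census columns are `NA`
#'   and `satisfied` is `FALSE`.
#' @export
tune_parameters <- function(model, constraint = "bistable_cyclic",
                            scheme = c("priority", "asynchronous", "synchronous"),
                            inputs = NULL, slots = NULL, prefilter = TRUE,
                            max_candidates = 100000L) {
  scheme <- match.arg(scheme)
  space <- parameter_space(model, slots)
  if (space$count > max_candidates)
    stop("parameter space has ", space$count, " candidates, above max_candidates")
  builtin <- identical(constraint, "bistable_cyclic")
  pred <- if (builtin) {
    function(census) census$n_cyclic == 2L && census$n_stationary == 0L
  } else {
    stopifnot(is.function(constraint))
    function(census) isTRUE(constraint(census$attractors))
  }
  circuits <- enumerate_circuits(model$network)

  res <- data.frame(index = seq_len(space$count),
                    functional_negative = NA, functional_positive = NA,
                    n_cyclic = NA_integer_, n_stationary = NA_integer_,
                    satisfied = FALSE)
  for (i in seq_len(space$count)) {
    pars <- space$get(i)
    cand <- model; cand$parameters <- pars
    pp <- lapply(circuits, function(ci) circuit_parities(cand, ci))
    res$functional_negative[i] <- any(vapply(pp, function(p) "-" %in% p, TRUE))
    res$functional_positive[i] <- any(vapply(pp, function(p) "+" %in% p, TRUE))
    if (prefilter && builtin &&
        !(res$functional_negative[i] && res$functional_positive[i])) next
    census <- attractor_census(model, pars, scheme, inputs)
    res$n_cyclic[i] <- census$n_cyclic
    res$n_stationary[i] <- census$n_stationary
    res$satisfied[i] <- pred(census)
  }
  attr(res, "space") <- space
  attr(res, "scheme") <- scheme
  class(res) <- c("mv_tuning", class(res))
  res
}

#' Calibrate the contexts of an environmental input
#'
#' Given a model containing an input node wired to one target, enumerates
#' every K assignment of the target's context slots (16 for a binary target
#' with two regulators), and classifies each candidate by its attractor
#' census with the input held active, and by whether with the input inactive
#' it reproduces the base model's attractor report. Candidates are *retained*
#' when they are rest-compatible and at least one of their input-active
#' stationary states projects onto a state of a resting attractor cycle
#' (stress-potentiated stable states overlapping the resting regimes).
#'
#' @param model an `mv_model`; if `input` is not yet a node, the classic
#'   stressor wiring (activating edge, threshold 1, onto `target`) is added.
#' @param input name of the input node.
#' @param scheme update scheme for all attractor reports.
#' @param target node the input acts on (required only when the input node
#'   has to be added).
#' @return An object of class `mv_calibration`: list with `table` (one row
#'   per candidate: census, rest-compatibility, overlap and retention flags),
#'   `params` (the candidate K tables for the target node), `reference` (the
#'   resting attractor report), `retained` (indices) and `retained_params`
#'   (named `normal` — a cyclic attractor survives under the input — and
#'   `heightened` — stationary points only).
#' @export
calibrate_input <- function(model, input,
                            scheme = c("priority", "asynchronous", "synchronous"),
                            target = NULL) {
  scheme <- match.arg(scheme)
  net <- model$network
  if (!(input %in% net$nodes$name)) {
    if (is.null(target)) stop("input node not in model; supply `target` to add it")
    net2 <- logical_network(
      nodes = rbind(net$nodes[c("name", "max_level")],
                    data.frame(name = input, max_level = 1L)),
      interactions = rbind(net$interactions,
                           data.frame(source = input, target = target,
                                      sign = "+", threshold = 1L)))
    pars <- model$parameters
    # extend the target's K table to the doubled context space (input-active
    # contexts start at the base value; they are all re-enumerated anyway)
    base_t <- pars[[target]]
    ext <- integer(0)
    for (s in seq_along(base_t)) {
      ctx <- names(base_t)[s]
      ext[[ctx]] <- base_t[[s]]
      ext[[context_key(c(if (nzchar(ctx)) strsplit(ctx, ",")[[1]], input))]] <- base_t[[s]]
    }
    pars[[target]] <- ext
    model <- logical_model(net2, pars,
                           delays = c(model$delays,
                                      stats::setNames(1L, input)))
    net <- model$network
  }
  if (!net$nodes$is_input[net$nodes$name == input])
    stop(input, " is not an input node (it has incoming interactions)")
  targets <- unique(net$interactions$target[net$interactions$source == input])
  if (length(targets) != 1L)
    stop("calibration expects the input to act on exactly one target node")
  target <- targets

  other_inputs <- setdiff(net$nodes$name[net$nodes$is_input], input)
  if (length(other_inputs))
    stop("calibration with additional input nodes is not supported")

  # reference: the resting report (input off), unaffected by the enumerated
  # input-active contexts of the base parameterization
  base_off <- find_attractors(build_stg(model, scheme,
                                        inputs = stats::setNames(list(0L), input)))
  x_cols <- setdiff(net$nodes$name, input)
  proj_labels <- function(att) lapply(att, function(a)
    sort(state_label(a$states[, x_cols, drop = FALSE])))
  ref_labels <- proj_labels(base_off)
  ref_cycle_states <- sort(unlist(ref_labels[
    vapply(base_off, `[[`, "", "kind") == "cyclic"]))

  slots <- data.frame(node = target,
                      context = vapply(all_subsets(net$regulators[[target]]),
                                       context_key, ""),
                      stringsAsFactors = FALSE)
  space <- parameter_space(model, slots)

  rows <- vector("list", space$count)
  params <- vector("list", space$count)
  for (i in seq_len(space$count)) {
    pars <- space$get(i)
    params[[i]] <- pars[[target]]
    cand <- model; cand$parameters <- pars
    att_on <- find_attractors(build_stg(cand, scheme,
                                        inputs = stats::setNames(list(1L), input)))
    kinds <- vapply(att_on, `[[`, "", "kind")
    stat_lab <- unlist(lapply(att_on[kinds == "stationary"], function(a)
      state_label(a$states[, x_cols, drop = FALSE])))
    att_off <- find_attractors(build_stg(cand, scheme,
                                         inputs = stats::setNames(list(0L), input)))
    rest_ok <- setequal(vapply(proj_labels(att_off), paste, collapse = ";", ""),
                        vapply(ref_labels, paste, collapse = ";", ""))
    on_cycle <- intersect(stat_lab, ref_cycle_states)
    rows[[i]] <- data.frame(
      index = i,
      n_cyclic = sum(kinds == "cyclic"),
      n_stationary = sum(kinds == "stationary"),
      stationary = paste(sort(stat_lab), collapse = " "),
      rest_compatible = rest_ok,
      stationary_on_resting_cycle = length(on_cycle) > 0L,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$retained <- tab$rest_compatible & tab$stationary_on_resting_cycle
  retained <- tab$index[tab$retained]

  retained_params <- list()
  for (i in retained) {
    tone <- if (tab$n_cyclic[i] > 0L) "normal" else "heightened"
    if (is.null(retained_params[[tone]])) retained_params[[tone]] <- params[[i]]
  }

  structure(list(table = tab, params = params, input = input, target = target,
                 scheme = scheme, reference = base_off, retained = retained,
                 retained_params = retained_params, model = model),
            class = "mv_calibration")
}

#' @export
print.mv_calibration <- function(x, ...) {
  cat("Input calibration of", x$input, "->", x$target, "(", x$scheme, "update )\n")
  cat(nrow(x$table), "candidate K assignments; census with", x$input, "= 1:\n")
  census <- table(paste0(x$table$n_cyclic, " cyclic + ",
                         x$table$n_stationary, " stationary"))
  for (nm in names(census)) cat(sprintf("  %-28s %d sets\n", nm, census[[nm]]))
  cat(sum(x$table$rest_compatible), "rest-compatible;",
      length(x$retained), "retained:", paste(x$retained, collapse = ", "), "\n")
  for (tone in names(x$retained_params)) {
    k <- x$retained_params[[tone]]
    cat("  ", tone, ": ",
        paste0("K{", names(k), "}=", k, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
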