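#' Tendency: single-step move of a state toward its image
#'
#' Each node moves one level toward its image per update (never a jump), so
#' trajectories pass through every intermediate level.
#'
#' @param state named integer vector of levels.
#' @param image image vector as returned by [state_image()].
#' @return named integer vector `f` with `f_i = x_i + sign(y_i - x_i)`.
#' @export
tendency <- function(state, image) {
  stopifnot(length(state) == length(image))
  f <- as.integer(as.integer(state) + sign(as.integer(image) - as.integer(state)))
  names(f) <- names(state)
  f
}

#' Synchronous successor of a state
#'
#' Every non-input node simultaneously takes its tendency value; the map is
#' deterministic and returns the state itself exactly at image fixed points.
#'
#' @param model an `mv_model`.
#' @param state a state vector.
#' @return the unique successor state (named integer vector).
#' @export
successors_synchronous <- function(model, state) {
  s <- as_state(model$network, state)
  y <- state_image(model, s)
  f <- tendency(s, y)
  stats::setNames(as.integer(f), names(s))
}

#' Fully asynchronous successors of a state
#'
#' One successor per non-input node whose tendency differs from its level;
#' each successor changes exactly that node by one level. A state with no
#' successor is stationary.
#'
#' @inheritParams successors_synchronous
#' @return list of successor states (possibly empty).
#' @export
successors_asynchronous <- function(model, state) {
  s <- as_state(model$network, state)
  y <- state_image(model, s)
  f <- tendency(s, y)
  movers <- which(f != s & !model$network$nodes$is_input)
  lapply(movers, function(i) { s2 <- s; s2[i] <- f[i]; s2 })
}

#' Initial extended state for the priority-with-memory scheme
#'
#' An extended state carries the levels `x`, per-node residual memory
#' counters `m` (initialized at the configured delays `d`), and the previous
#' image `y_prev` (`NULL` at the start of a run, where the image-agreement
#' flag F1 is defined false).
#'
#' @inheritParams successors_synchronous
#' @return list with elements `x`, `m`, `y_prev`.
#' @export
extended_state <- function(model, state) {
  s <- as_state(model$network, state)
  list(x = s, m = stats::setNames(model$delays[names(s)], names(s)),
       y_prev = NULL)
}

#' Residual-memory update rule
#'
#' Per node, with F1 = (previous image differs from current image) and
#' F2 = (the node's level is unchanged in the transition):
#' `m <- min(d, m + 1)` if F1 and F2; `m <- max(1, m - 1)` if not-F1 and F2;
#' `m <- d` if not-F2 (the node was just updated). At the start of a run F1
#' is false for every node.
#'
#' @param ext an extended state (see [extended_state()]).
#' @param y_now current image vector.
#' @param x_next the levels after the transition.
#' @param delays named integer vector of per-node delays.
#' @return named integer vector of new memory counters.
#' @export
update_memory <- function(ext, y_now, x_next, delays) {
  d <- as.integer(delays[names(ext$x)])
  m <- as.integer(ext$m)
  f1 <- if (is.null(ext$y_prev)) rep(FALSE, length(m)) else
    as.integer(ext$y_prev) != as.integer(y_now)
  f2 <- as.integer(ext$x) == as.integer(x_next)
  m_new <- ifelse(!f2, d,
           ifelse(f1, pmin(d, m + 1L), pmax(1L, m - 1L)))
  stats::setNames(as.integer(m_new), names(ext$x))
}

#' Nodes eligible for update under the priority-with-memory scheme
#'
#' The non-input nodes whose residual memory attains the minimum over all
#' non-input nodes (ties are all eligible).
#'
#' @param model an `mv_model`.
#' @param ext an extended state.
#' @return character vector of eligible node names.
#' @export
eligible_nodes <- function(model, ext) {
  ni <- !model$network$nodes$is_input
  nm <- model$network$nodes$name
  m <- ext$m[nm]
  cand <- nm[ni]
  cand[m[cand] == min(m[cand])]
}

#' Priority-with-memory successors of an extended state
#'
#' One successor per eligible node whose tendency changes its level, each
#' changing exactly that node by one level and carrying updated memory
#' counters and the current image as `y_prev`. When no eligible node can
#' move but some non-eligible node is off its image, a single "idle"
#' successor is produced in which only the memory counters advance (this is
#' how a slow node's delay is consumed). Image fixed points are stationary:
#' they have no successor.
#'
#' @inheritParams eligible_nodes
#' @return list of successor extended states (possibly empty).
#' @export
successors_priority <- function(model, ext) {
  s <- ext$x
  y <- state_image(model, s)
  f <- tendency(s, y)
  ni <- !model$network$nodes$is_input
  if (all(f[ni] == s[ni])) return(list())   # stationary
  elig <- eligible_nodes(model, ext)
  movers <- elig[f[elig] != s[elig]]
  if (!length(movers)) {
    m2 <- update_memory(ext, y, s, model$delays)
    return(list(list(x = s, m = m2, y_prev = y)))
  }
  lapply(movers, function(v) {
    s2 <- s; s2[v] <- f[v]
    list(x = s2, m = update_memory(ext, y, s2, model$delays), y_prev = y)
  })
}

#' Simulate one trajectory under a chosen update scheme
#'
#' Branch points (asynchronous and priority schemes) are resolved by uniform
#' random choice among successors, reproducibly under `seed`.
#'
#' @param model an `mv_model`.
#' @param init initial state.
#' @param scheme one of `"synchronous"`, `"asynchronous"`, `"priority"`.
#' @param n_steps number of transitions to attempt (>= 0); the trajectory is
#'   cut short at a stationary state.
#' @param seed integer seed (required for the nondeterministic schemes).
#' @return integer matrix with one row per visited state (including `init`),
#'   columns named by node.
#' @export
simulate_trajectory <- function(model, init, scheme = c("priority", "asynchronous", "synchronous"),
                                n_steps = 50, seed = NULL) {
  scheme <- match.arg(scheme)
  if (n_steps < 0) stop("n_steps must be >= 0")
  if (scheme != "synchronous") {
    if (is.null(seed)) stop("seed is required for scheme ", scheme)
    set.seed(seed)
  }
  s <- as_state(model$network, init)
  traj <- matrix(s, nrow = 1L, dimnames = list(NULL, names(s)))
  ext <- if (scheme == "priority") extended_state(model, s) else NULL
  for (k in seq_len(n_steps)) {
    nxt <- switch(scheme,
      synchronous = {
        s2 <- successors_synchronous(model, s)
        if (all(s2 == s)) NULL else s2
      },
      asynchronous = {
        succ <- successors_asynchronous(model, s)
        if (!length(succ)) NULL else succ[[sample.int(length(succ), 1L)]]
      },
      priority = {
        succ <- successors_priority(model, ext)
        if (!length(succ)) NULL else {
          ext <- succ[[sample.int(length(succ), 1L)]]
          ext$x
        }
      })
    if (is.null(nxt)) break
    s <- stats::setNames(as.integer(nxt), names(s))
    traj <- rbind(traj, s)
  }
  rownames(traj) <- NULL
  traj
}
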