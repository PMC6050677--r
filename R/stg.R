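#' Bracket label of a state
#'
#' Concatenates the node levels in node order, e.g. `"[0002]"`.
#'
#' @param state integer vector or matrix of states (rows).
#' @return character vector of labels.
#' @export
state_label <- function(state) {
  if (is.matrix(state))
    apply(state, 1L, function(r) paste0("[", paste0(r, collapse = ""), "]"))
  else paste0("[", paste0(state, collapse = ""), "]")
}

# mixed-radix encoding of state rows (vectorized); base weights from max levels
state_codes <- function(S, rho) {
  w <- rev(cumprod(rev(c(rho[-1] + 1, 1))))
  as.integer(S %*% w)
}

#' Build the full state transition graph under an update scheme
#'
#' Vertices enumerate the whole state space for a fixed input assignment
#' (for the priority scheme, the reachable memory-extended space seeded from
#' every state with memory counters at their delays). Edges are the scheme's
#' successor relation.
#'
#' @param model an `mv_model`.
#' @param scheme `"synchronous"`, `"asynchronous"` or `"priority"`.
#' @param inputs named list/vector fixing the level of every input node
#'   (may be `NULL` when the network has no inputs).
#' @param max_states refuse to build graphs larger than this many vertices
#'   (exhaustive traversal is exponential in network size).
#' @return An object of class `mv_stg`: list with `states` (vertex levels,
#'   one row per vertex), `edges` (per-vertex integer vector of successor
#'   vertex ids), `scheme`, `inputs`, and for the priority scheme the memory
#'   matrix `m`, previous-image matrix and `initial` (vertex id of the
#'   run-start vertex of each x-state).
#' @export
build_stg <- function(model, scheme = c("priority", "asynchronous", "synchronous"),
                      inputs = NULL, max_states = 50000L) {
  scheme <- match.arg(scheme)
  cm <- compile_model(model)
  S <- enumerate_states(model, inputs)
  n_states <- nrow(S)
  if (n_states > max_states)
    stop("state space has ", n_states, " states, above max_states = ", max_states)
  rho <- cm$rho
  ni <- which(!cm$is_input)

  if (scheme != "priority") {
    out <- list(states = S, edges = rep(list(integer()), n_states),
                scheme = scheme, inputs = inputs,
                extended = FALSE, initial = seq_len(n_states), model = model)
    class(out) <- "mv_stg"
    if (scheme == "synchronous") {
      codes <- state_codes(S, rho)
      row_of <- integer(max(codes) + 1L); row_of[codes + 1L] <- seq_len(n_states)
      Y <- image_matrix(model, S)
      Fm <- S + sign(Y - S)
      out$edges <- as.list(row_of[state_codes(Fm, rho) + 1L])
    } else {
      out <- build_async_edges(out, cm)
    }
    return(out)
  }

  build_priority_stg(model, cm, S, inputs, max_states)
}

# asynchronous edges, vectorized per node
build_async_edges <- function(stg, cm) {
  S <- stg$states
  rho <- cm$rho
  codes <- state_codes(S, rho)
  row_of <- integer(max(codes) + 1L); row_of[codes + 1L] <- seq_len(nrow(S))
  w <- rev(cumprod(rev(c(rho[-1] + 1, 1))))
  Y <- image_matrix(stg$model, S)
  Fm <- S + sign(Y - S)
  edges <- rep(list(integer()), nrow(S))
  for (i in which(!cm$is_input)) {
    delta <- Fm[, i] - S[, i]
    mv <- which(delta != 0L)
    if (!length(mv)) next
    succ <- row_of[codes[mv] + delta[mv] * w[i] + 1L]
    for (k in seq_along(mv)) edges[[mv[k]]] <- c(edges[[mv[k]]], succ[k])
  }
  stg$edges <- edges
  stg
}

# exhaustive reachable extended graph for the priority-with-memory scheme
build_priority_stg <- function(model, cm, S, inputs, max_states) {
  nm <- cm$names
  n <- cm$n
  d <- cm$delays
  ni <- which(!cm$is_input)

  # y_prev sentinel (start of run, F1 defined false) is stored as NA levels
  key_of <- function(x, m, yp)
    paste(paste0(x, collapse = ""), paste0(m, collapse = ""),
          paste0(yp, collapse = ""), sep = "|")

  env <- new.env(hash = TRUE, parent = emptyenv())
  xs <- list(); ms <- list(); yps <- list()
  edges <- list()
  queue <- list()
  sentinel <- rep(NA_integer_, n)
  add_vertex <- function(x, m, yp) {
    k <- key_of(x, m, yp)
    id <- env[[k]]
    if (!is.null(id)) return(id)
    id <- length(xs) + 1L
    if (id > max_states) stop("extended state space exceeds max_states = ", max_states)
    env[[k]] <- id
    xs[[id]] <<- x; ms[[id]] <<- m; yps[[id]] <<- yp
    queue[[length(queue) + 1L]] <<- id
    id
  }

  initial <- integer(nrow(S))
  for (v in seq_len(nrow(S))) initial[v] <- add_vertex(S[v, ], d, sentinel)

  head <- 1L
  while (head <= length(queue)) {
    id <- queue[[head]]; head <- head + 1L
    x <- xs[[id]]; m <- ms[[id]]; yp <- yps[[id]]
    y <- image_compiled(cm, x)
    f <- as.integer(x + sign(y - x))
    if (all(f[ni] == x[ni])) { edges[[id]] <- integer(); next }
    mmin <- min(m[ni])
    elig <- ni[m[ni] == mmin]
    movers <- elig[f[elig] != x[elig]]
    f1 <- !is.na(yp) & yp != y
    succ <- integer()
    if (!length(movers)) {
      # idle: only memory advances while a slow node's delay is consumed
      m2 <- ifelse(f1, pmin(d, m + 1L), pmax(1L, m - 1L))
      succ <- add_vertex(x, as.integer(m2), y)
    } else {
      for (i in movers) {
        x2 <- x; x2[i] <- f[i]
        f2 <- x2 == x
        m2 <- ifelse(!f2, d, ifelse(f1, pmin(d, m + 1L), pmax(1L, m - 1L)))
        succ <- c(succ, add_vertex(x2, as.integer(m2), y))
      }
    }
    edges[[id]] <- succ
  }
  n_v <- length(xs)
  length(edges) <- n_v
  edges[vapply(edges, is.null, TRUE)] <- list(integer())
  V <- do.call(rbind, xs)
  colnames(V) <- nm
  M <- do.call(rbind, ms)
  colnames(M) <- nm
  structure(list(states = V, edges = edges, scheme = "priority",
                 inputs = inputs, extended = TRUE, m = M, initial = initial,
                 x_space = S, model = model),
            class = "mv_stg")
}

#' @export
print.mv_stg <- function(x, ...) {
  ne <- sum(lengths(x$edges))
  cat("State transition graph (", x$scheme, " update): ",
      nrow(x$states), " vertices, ", ne, " edges",
      if (x$extended) " [memory-extended]", "\n", sep = "")
  invisible(x)
}

# iterative Tarjan SCC; returns integer vector of component ids (1-based,
# in reverse topological order of discovery)
tarjan_scc <- function(edges) {
  n <- length(edges)
  index <- rep(NA_integer_, n); low <- integer(n)
  on_stack <- logical(n); stack <- integer(0)
  comp <- rep(NA_integer_, n); n_comp <- 0L; counter <- 0L
  for (root in seq_len(n)) {
    if (!is.na(index[root])) next
    # explicit DFS stack: vertex + position in its successor list
    dfs_v <- root; dfs_i <- 0L; depth <- 1L
    vstack <- integer(n); istack <- integer(n)
    vstack[1L] <- root; istack[1L] <- 0L
    counter <- counter + 1L
    index[root] <- counter; low[root] <- counter
    stack <- c(stack, root); on_stack[root] <- TRUE
    while (depth > 0L) {
      v <- vstack[depth]; i <- istack[depth]
      succ <- edges[[v]]
      if (i < length(succ)) {
        istack[depth] <- i + 1L
        w <- succ[i + 1L]
        if (is.na(index[w])) {
          counter <- counter + 1L
          index[w] <- counter; low[w] <- counter
          stack <- c(stack, w); on_stack[w] <- TRUE
          depth <- depth + 1L
          vstack[depth] <- w; istack[depth] <- 0L
        } else if (on_stack[w]) {
          low[v] <- min(low[v], index[w])
        }
      } else {
        if (low[v] == index[v]) {
          n_comp <- n_comp + 1L
          repeat {
            w <- stack[length(stack)]; stack <- stack[-length(stack)]
            on_stack[w] <- FALSE; comp[w] <- n_comp
            if (w == v) break
          }
        }
        depth <- depth - 1L
        if (depth > 0L) {
          u <- vstack[depth]
          low[u] <- min(low[u], low[v])
        }
      }
    }
  }
  comp
}

#' Identify attractors: terminal strongly connected components
#'
#' Attractors are the strongly connected components of the state transition
#' graph with no edge leaving the component. A single state with no
#' change-producing successor is a *stationary* (regular) attractor; a
#' terminal component with two or more states (or an internal cycle) is a
#' *cyclic* (singular) attractor. For memory-extended graphs the attractor
#' states are projected to level space; projected attractors identical in
#' level space are merged.
#'
#' @param stg an `mv_stg` from [build_stg()].
#' @return An object of class `mv_attractors`: list of attractors, each with
#'   `id`, `kind` (`"stationary"`/`"cyclic"`), `states` (matrix of distinct
#'   level-space states) and `vertices` (vertex ids in the graph).
#' @export
find_attractors <- function(stg) {
  comp <- tarjan_scc(stg$edges)
  n_comp <- max(comp)
  # terminal = no edge to a different component
  terminal <- rep(TRUE, n_comp)
  for (v in seq_along(stg$edges)) {
    out_comp <- comp[stg$edges[[v]]]
    if (any(out_comp != comp[v])) terminal[comp[v]] <- FALSE
  }
  atts <- list()
  for (cidx in which(terminal)) {
    vids <- which(comp == cidx)
    # synchronous fixed points map to themselves; treat identity self-loop
    # (or no successor) on a singleton as stationary
    kind <- if (length(vids) == 1L &&
                (length(stg$edges[[vids]]) == 0L || all(stg$edges[[vids]] == vids)))
      "stationary" else "cyclic"
    states <- unique(stg$states[vids, , drop = FALSE])
    atts[[length(atts) + 1L]] <- list(kind = kind, states = states,
                                      vertices = vids)
  }
  if (stg$extended) {
    # merge attractors with identical level-space projection
    keys <- vapply(atts, function(a)
      paste(sort(state_label(a$states)), collapse = ";"), "")
    merged <- list()
    for (k in unique(keys)) {
      grp <- atts[keys == k]
      states <- grp[[1L]]$states
      merged[[length(merged) + 1L]] <- list(
        kind = if (nrow(states) == 1L) "stationary" else grp[[1L]]$kind,
        states = states,
        vertices = sort(unlist(lapply(grp, `[[`, "vertices"))))
    }
    atts <- merged
  }
  # stable order: by smallest state label
  ord <- order(vapply(atts, function(a) min(state_label(a$states)), ""))
  atts <- atts[ord]
  for (i in seq_along(atts)) atts[[i]]$id <- i
  structure(atts, class = "mv_attractors", scheme = stg$scheme)
}

#' @export
print.mv_attractors <- function(x, ...) {
  cat(length(x), "attractor(s) under", attr(x, "scheme"), "update:\n")
  for (a in x) {
    cat(sprintf("  #%d %s (%d state%s): %s\n", a$id, a$kind, nrow(a$states),
                if (nrow(a$states) == 1L) "" else "s",
                paste(sort(state_label(a$states)), collapse = " ")))
  }
  invisible(x)
}

#' Basins of attraction
#'
#' Computes, for every state of the graph, the set of attractors reachable
#' from it (backward traversal from each attractor). A state whose set is a
#' singleton belongs *exclusively* to that attractor's basin; under
#' nondeterministic schemes a state may reach several attractors.
#'
#' @param stg an `mv_stg`.
#' @param attractors the result of [find_attractors()] on `stg`.
#' @return An object of class `mv_basins`: data frame with one row per
#'   level-space state (`label`), the reachable attractor ids
#'   (`reachable`, list column) and `basin` (the attractor id when exclusive,
#'   `NA` otherwise).
#' @export
compute_basins <- function(stg, attractors) {
  n <- length(stg$edges)
  # reverse adjacency
  radj <- rep(list(integer()), n)
  for (v in seq_len(n)) for (w in stg$edges[[v]])
    radj[[w]] <- c(radj[[w]], v)
  reach <- matrix(FALSE, n, length(attractors))
  for (a in attractors) {
    seen <- logical(n)
    queue <- a$vertices
    seen[queue] <- TRUE
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (u in radj[[v]]) if (!seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
    }
    reach[, a$id] <- seen
  }
  # per level-space state: reachable set from its run-start vertex
  init <- stg$initial
  S <- if (stg$extended) stg$x_space else stg$states
  labels <- state_label(S)
  rlist <- lapply(seq_along(init), function(i) which(reach[init[i], ]))
  excl <- vapply(rlist, function(r) if (length(r) == 1L) r else NA_integer_,
                 integer(1))
  out <- data.frame(label = labels, basin = excl, stringsAsFactors = FALSE)
  out$reachable <- rlist
  attr(out, "vertex_reach") <- reach
  class(out) <- c("mv_basins", class(out))
  out
}
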