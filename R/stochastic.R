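#' Activity vector: which nodes receive at least one active interaction
#'
#' A node can fault only while it is dynamically active, i.e. it has at least
#' one incoming interaction whose source is at or above the interaction
#' threshold (the level test is `x >= theta` for inhibitory edges too; input
#' nodes have no incoming interaction and are never active).
#'
#' @param model an `mv_model`.
#' @param state a state vector.
#' @return named logical vector, `TRUE` for active nodes.
#' @export
active_nodes <- function(model, state) {
  net <- model$network
  s <- as_state(net, state)
  beta <- stats::setNames(rep(FALSE, nrow(net$nodes)), net$nodes$name)
  ia <- net$interactions
  hot <- s[ia$source] >= ia$threshold
  for (v in unique(ia$target[hot])) beta[v] <- TRUE
  beta
}

#' Faulty tendency of a node
#'
#' Inverts the node's obedience to its image: when commanded to move it holds
#' still; at equilibrium it is displaced, upward from level 0, downward from
#' its maximum, and to either neighbor (uniform choice) from an interior
#' level.
#'
#' @param state state vector.
#' @param image image vector.
#' @param node node name.
#' @param max_level the node's maximum level.
#' @return integer vector of candidate faulty levels (length 1, or length 2
#'   for the interior-equilibrium case; the simulator picks uniformly).
#' @export
faulty_tendency <- function(state, image, node, max_level) {
  x <- state[[node]]; y <- image[[node]]
  if (x != y) return(x)
  if (x == 0L) return(x + 1L)
  if (x == max_level) return(x - 1L)
  c(x - 1L, x + 1L)
}

# ---------------------------------------------------------------------------
# Fault kernel: the extended state space closed under normal and single-fault
# transitions, with per-vertex successor distributions at fault rate eps and
# at eps = 0, and the eps = 0 terminal components labeled by attractor.
# ---------------------------------------------------------------------------

#' Precompute the faulted transition kernel of a model
#'
#' Enumerates every (extended) state reachable from the run-start states
#' under the chosen scheme when, per iteration, one active node is selected
#' uniformly and with probability `eps` disobeys its tendency
#' ([faulty_tendency()]). For each state the successor distribution is
#' tabulated at rate `eps` and at rate 0, and the terminal strongly connected
#' components of the fault-free dynamics are matched to the model's
#' attractors, so that Monte Carlo runs reduce to indexed walks.
#'
#' @param model an `mv_model`.
#' @param scheme `"priority"` or `"asynchronous"`.
#' @param inputs input assignment.
#' @param eps per-iteration fault probability in [0, 1].
#' @param max_states cap on the closure size.
#' @return an object of class `mv_fault_kernel` (used by
#'   [run_with_faults()] and [attractor_transition_matrix()]).
#' @export
fault_kernel <- function(model, scheme = c("priority", "asynchronous"),
                         inputs = NULL, eps = 0.05, max_states = 200000L) {
  scheme <- match.arg(scheme)
  if (eps < 0 || eps > 1) stop("eps must be in [0, 1]")
  cm <- compile_model(model)
  n <- cm$n
  ni <- which(!cm$is_input)
  d <- cm$delays
  rho <- cm$rho
  S <- enumerate_states(model, inputs)

  # interaction table for the activity vector
  ia <- model$network$interactions
  ia_src <- match(ia$source, cm$names)
  ia_tgt <- match(ia$target, cm$names)
  ia_thr <- ia$threshold

  has_memory <- scheme == "priority"
  sentinel <- rep(NA_integer_, n)

  env <- new.env(hash = TRUE, parent = emptyenv())
  xs <- list(); ms <- list(); yps <- list()
  queue <- integer(0)
  key_of <- function(x, m, yp)
    paste(paste0(x, collapse = ""), paste0(m, collapse = ""),
          paste0(yp, collapse = ""), sep = "|")
  add_vertex <- function(x, m, yp) {
    k <- key_of(x, m, yp)
    id <- env[[k]]
    if (!is.null(id)) return(id)
    id <- length(xs) + 1L
    if (id > max_states) stop("fault-kernel state space exceeds max_states")
    env[[k]] <- id
    xs[[id]] <<- x; ms[[id]] <<- m; yps[[id]] <<- yp
    queue[[length(queue) + 1L]] <<- id
    id
  }

  initial <- integer(nrow(S))
  m0 <- if (has_memory) d else rep(1L, n)
  yp0 <- if (has_memory) sentinel else NULL
  for (v in seq_len(nrow(S)))
    initial[v] <- add_vertex(S[v, ], m0, yp0)

  # successor distribution given a tendency vector f (memory rules use the
  # true image y); returns list(ids, w) with weights summing to 1
  scheme_succs <- function(id, x, m, yp, y, f) {
    if (has_memory) {
      f1 <- !is.na(yp) & yp != y
      mmin <- min(m[ni])
      elig <- ni[m[ni] == mmin]
      movers <- elig[f[elig] != x[elig]]
      if (!length(movers)) {
        # idle iteration: memory still advances (self-loop once it bottoms
        # out at a fixed point with settled image)
        m2 <- as.integer(ifelse(f1, pmin(d, m + 1L), pmax(1L, m - 1L)))
        id2 <- add_vertex(x, m2, y)
        return(list(ids = id2, w = 1))
      }
      ids <- vapply(movers, function(i) {
        x2 <- x; x2[i] <- f[i]
        f2 <- x2 == x
        m2 <- as.integer(ifelse(!f2, d, ifelse(f1, pmin(d, m + 1L),
                                               pmax(1L, m - 1L))))
        add_vertex(x2, m2, y)
      }, integer(1))
      list(ids = ids, w = rep(1 / length(ids), length(ids)))
    } else {
      movers <- ni[f[ni] != x[ni]]
      if (!length(movers)) return(list(ids = id, w = 1))
      ids <- vapply(movers, function(i) {
        x2 <- x; x2[i] <- f[i]
        add_vertex(x2, rep(1L, n), NULL)
      }, integer(1))
      list(ids = ids, w = rep(1 / length(ids), length(ids)))
    }
  }

  succ_eps <- list(); succ0 <- list()
  head <- 1L
  while (head <= length(queue)) {
    id <- queue[[head]]; head <- head + 1L
    x <- xs[[id]]; m <- ms[[id]]; yp <- yps[[id]]
    y <- image_compiled(cm, x)
    f <- as.integer(x + sign(y - x))

    # fault-free distribution
    nrm <- scheme_succs(id, x, m, yp, y, f)
    succ0[[id]] <- nrm

    # active nodes (Eq. of the activity vector; sign-blind level test)
    beta <- unique(ia_tgt[x[ia_src] >= ia_thr])
    if (!length(beta) || eps == 0) { succ_eps[[id]] <- nrm; next }

    acc_ids <- nrm$ids; acc_w <- nrm$w * (1 - eps)
    p_v <- eps / length(beta)
    for (v in beta) {
      # faulty branch(es) for node v
      cand <- if (x[v] != y[v]) x[v]
              else if (x[v] == 0L) 1L
              else if (x[v] == rho[v]) x[v] - 1L
              else c(x[v] - 1L, x[v] + 1L)
      for (fv in cand) {
        f2 <- f; f2[v] <- fv
        br <- scheme_succs(id, x, m, yp, y, f2)
        acc_ids <- c(acc_ids, br$ids)
        acc_w <- c(acc_w, br$w * p_v / length(cand))
      }
    }
    agg <- rowsum(acc_w, acc_ids)
    succ_eps[[id]] <- list(ids = as.integer(rownames(agg)), w = as.numeric(agg))
  }

  n_v <- length(xs)
  V <- do.call(rbind, xs); colnames(V) <- cm$names

  # eps = 0 terminal components -> attractor labels
  edges0 <- lapply(succ0, `[[`, "ids")
  comp <- tarjan_scc(edges0)
  terminal <- rep(TRUE, max(comp))
  for (v in seq_len(n_v))
    if (any(comp[edges0[[v]]] != comp[v])) terminal[comp[v]] <- FALSE
  attr_of <- integer(n_v)   # 0 = transient
  term_proj <- list()
  for (cidx in which(terminal)) {
    vids <- which(comp == cidx)
    key <- paste(sort(unique(state_label(V[vids, , drop = FALSE]))), collapse = ";")
    aid <- match(key, names(term_proj))
    if (is.na(aid)) {
      term_proj[[key]] <- length(term_proj) + 1L
      aid <- term_proj[[key]]
    } else aid <- term_proj[[key]]
    attr_of[vids] <- aid
  }

  structure(list(states = V, initial = initial, succ_eps = succ_eps,
                 succ0 = succ0, attractor_of = attr_of,
                 attractor_keys = names(term_proj), eps = eps,
                 scheme = scheme, inputs = inputs, model = model),
            class = "mv_fault_kernel")
}

#' @export
print.mv_fault_kernel <- function(x, ...) {
  cat("Fault kernel (", x$scheme, " update, eps = ", x$eps, "): ",
      nrow(x$states), " reachable states, ",
      length(x$attractor_keys), " terminal structure(s)\n", sep = "")
  invisible(x)
}

# one vectorized step of many chains over a successor table
step_chains <- function(cur, succ) {
  for (grp in split(seq_along(cur), cur)) {
    s <- succ[[cur[grp[1L]]]]
    k <- length(s$ids)
    cur[grp] <- if (k == 1L) s$ids else
      s$ids[sample.int(k, length(grp), replace = TRUE, prob = s$w)]
  }
  cur
}

# walk chains with the eps kernel for `horizon` steps, then relax at eps = 0
# until every chain sits in a terminal structure; returns attractor key index
run_chains <- function(kernel, start_ids, horizon, max_relax = 10000L) {
  cur <- start_ids
  for (t in seq_len(horizon)) cur <- step_chains(cur, kernel$succ_eps)
  alive <- which(kernel$attractor_of[cur] == 0L)
  it <- 0L
  while (length(alive)) {
    it <- it + 1L
    if (it > max_relax) stop("relaxation did not absorb within ", max_relax, " steps")
    cur[alive] <- step_chains(cur[alive], kernel$succ0)
    alive <- alive[kernel$attractor_of[cur[alive]] == 0L]
  }
  kernel$attractor_of[cur]
}

#' Simulate one faulted run and report the attractor it settles in
#'
#' Runs `horizon` iterations under fault rate `eps` (per iteration one
#' active node is selected uniformly and disobeys its tendency with
#' probability `eps`), then relaxes fault-free until an attractor is entered.
#'
#' @param model an `mv_model`.
#' @param init initial state.
#' @param eps fault probability per iteration.
#' @param horizon number of faulted iterations per run (> 0); the
#'   default of one fault opportunity per run follows the single-fault model.
#' @param seed integer seed.
#' @param scheme update scheme.
#' @param inputs input assignment.
#' @param kernel optionally a prebuilt [fault_kernel()] (must match `eps`,
#'   `scheme` and `inputs`).
#' @return the attractor id (index into `attractor_states(kernel)`), with the
#'   attractor's state labels as attribute `"states"`.
#' @export
run_with_faults <- function(model, init, eps = 0.05, horizon = 1, seed = 1,
                            scheme = c("priority", "asynchronous"),
                            inputs = NULL, kernel = NULL) {
  scheme <- match.arg(scheme)
  if (horizon <= 0) stop("horizon must be > 0")
  if (is.null(kernel))
    kernel <- fault_kernel(model, scheme, inputs, eps)
  set.seed(seed)
  S <- enumerate_states(model, inputs)
  v0 <- kernel$initial[match(state_label(as_state(model$network, init))[1],
                             state_label(S))]
  aid <- run_chains(kernel, v0, horizon)
  attr(aid, "states") <- strsplit(kernel$attractor_keys[aid], ";")[[1]]
  aid
}

#' Settling distribution of faulted runs from chosen start states
#'
#' Runs the [run_with_faults()] protocol `reps` times from each given start
#' state and tallies the attractors the runs settle in. Unlike
#' [attractor_transition_matrix()], the start states need not be grouped by
#' basin — useful e.g. for starting a perturbed model from the attractor
#' states of a reference condition.
#'
#' @param model an `mv_model`.
#' @param init_states matrix of start states (one per row) or a single state
#'   vector.
#' @param eps fault probability per iteration.
#' @param reps runs per start state.
#' @param horizon faulted iterations per run.
#' @param seed integer seed.
#' @param scheme update scheme.
#' @param inputs input assignment.
#' @return named numeric vector: per attractor (keyed by its sorted state
#'   labels), the fraction of all runs settling there; total run count in
#'   attribute `"n_runs"`.
#' @export
settle_distribution <- function(model, init_states, eps = 0.05, reps = 1000,
                                horizon = 1, seed = 1,
                                scheme = c("priority", "asynchronous"),
                                inputs = NULL) {
  scheme <- match.arg(scheme)
  if (!is.matrix(init_states))
    init_states <- matrix(as_state(model$network, init_states), nrow = 1L)
  kernel <- fault_kernel(model, scheme, inputs, eps)
  S <- enumerate_states(model, inputs)
  idx <- match(state_label(init_states), state_label(S))
  if (anyNA(idx)) stop("start state outside the model's state space")
  set.seed(seed)
  start_ids <- rep(kernel$initial[idx], each = reps)
  outcome <- run_chains(kernel, start_ids, horizon)
  tab <- table(factor(outcome, levels = seq_along(kernel$attractor_keys)))
  out <- as.numeric(tab) / length(start_ids)
  names(out) <- kernel$attractor_keys
  attr(out, "n_runs") <- length(start_ids)
  out
}

#' Monte Carlo estimate of the attractor transition matrix
#'
#' For every initial state belonging exclusively to one attractor's basin,
#' performs `reps` faulted runs ([run_with_faults()] protocol) and tallies,
#' by starting basin, the attractor each run settles in. Entry `(i, j)` of
#' the resulting matrix is the estimated probability of ending in attractor
#' `i` given a start in the basin of attractor `j`; columns sum to one.
#'
#' @param model an `mv_model`.
#' @param eps fault probability per iteration.
#' @param reps Monte Carlo repetitions per initial state.
#' @param horizon faulted iterations per run before fault-free relaxation
#'   (default: one fault opportunity per run, the single-fault protocol).
#' @param seed integer seed (identical settings and seed reproduce the
#'   matrix bit for bit).
#' @param scheme update scheme.
#' @param inputs input assignment.
#' @return An object of class `mv_transition_matrix`: list with `pi` (the
#'   column-stochastic matrix), `counts` (settled-run tallies), `n_runs` per
#'   basin, `attractors` (the fault-free attractor report) and `basins`.
#' @export
attractor_transition_matrix <- function(model, eps = 0.05, reps = 1000,
                                        horizon = 1, seed = 1,
                                        scheme = c("priority", "asynchronous"),
                                        inputs = NULL) {
  scheme <- match.arg(scheme)
  if (reps < 1) stop("reps must be >= 1")
  stg <- build_stg(model, scheme, inputs = inputs)
  att <- find_attractors(stg)
  basins <- compute_basins(stg, att)
  excl <- which(!is.na(basins$basin))
  if (!length(excl)) stop("no state belongs exclusively to one basin")

  kernel <- fault_kernel(model, scheme, inputs, eps)
  # map kernel terminal structures to reported attractors via state labels
  att_keys <- vapply(att, function(a)
    paste(sort(state_label(a$states)), collapse = ";"), "")
  kern2att <- match(kernel$attractor_keys, att_keys)
  if (anyNA(kern2att))
    stop("fault-free terminal structure not matching any reported attractor")

  set.seed(seed)
  start_ids <- rep(kernel$initial[excl], each = reps)
  start_basin <- rep(basins$basin[excl], each = reps)
  outcome <- kern2att[run_chains(kernel, start_ids, horizon)]

  k <- length(att)
  counts <- matrix(0L, k, k,
                   dimnames = list(settled = paste0("A", seq_len(k)),
                                   basin = paste0("A", seq_len(k))))
  tab <- table(factor(outcome, levels = seq_len(k)),
               factor(start_basin, levels = seq_len(k)))
  counts[] <- as.integer(tab)
  n_runs <- colSums(counts)
  pi_m <- sweep(counts, 2L, pmax(n_runs, 1L), "/")
  structure(list(pi = pi_m, counts = counts, n_runs = n_runs,
                 attractors = att, basins = basins, eps = eps, reps = reps,
                 horizon = horizon, seed = seed, scheme = scheme,
                 inputs = inputs),
            class = "mv_transition_matrix")
}

#' @export
print.mv_transition_matrix <- function(x, ...) {
  cat("Attractor transition matrix (eps = ", x$eps, ", ", x$reps,
      " reps/state, horizon ", x$horizon, "):\n", sep = "")
  print(round(x$pi, 4))
  for (a in x$attractors)
    cat(sprintf("  A%d: %s (%d state%s)\n", a$id, a$kind, nrow(a$states),
                if (nrow(a$states) == 1L) "" else "s"))
  invisible(x)
}

#' Evolve an attractor-occupancy distribution as a Markov chain
#'
#' Iterates `p(t+1) = Pi p(t)` for a column-stochastic attractor transition
#' matrix, tracking the full occupancy trajectory, the first step at which
#' the probability of having escaped the initially occupied attractor
#' reaches one half, and the limiting distribution.
#'
#' @param pi_matrix square column-stochastic matrix (or an
#'   `mv_transition_matrix`).
#' @param p0 initial distribution over attractors (or an attractor index).
#' @param n_steps number of steps to iterate.
#' @param tol tolerance for the limiting-distribution fixed point.
#' @return An object of class `mv_markov`: list with `distributions`
#'   (`(n_steps + 1) x k` matrix, row `t+1` is the distribution after `t`
#'   steps), `t_half` (first step with escape probability >= 0.5, `NA` if
#'   never within `n_steps`), and `limit`.
#' @export
markov_evolve <- function(pi_matrix, p0, n_steps = 100, tol = 1e-12) {
  P <- if (inherits(pi_matrix, "mv_transition_matrix")) pi_matrix$pi else as.matrix(pi_matrix)
  k <- nrow(P)
  if (ncol(P) != k) stop("transition matrix must be square")
  if (any(abs(colSums(P) - 1) > 1e-8)) stop("matrix columns must sum to 1")
  if (length(p0) == 1L && p0 == round(p0)) {
    i0 <- as.integer(p0); p0 <- rep(0, k); p0[i0] <- 1
  }
  if (abs(sum(p0) - 1) > 1e-8) stop("p0 must be a probability distribution")
  home <- which.max(p0)
  dist <- matrix(NA_real_, n_steps + 1L, k)
  dist[1L, ] <- p0
  p <- p0
  for (t in seq_len(n_steps)) {
    p <- as.numeric(P %*% p)
    dist[t + 1L, ] <- p
  }
  esc <- 1 - dist[, home]
  t_half <- which(esc >= 0.5)[1L] - 1L
  # limiting distribution: iterate to a fixed point
  p <- if (any(is.na(dist[n_steps + 1L, ]))) p0 else dist[n_steps + 1L, ]
  for (it in seq_len(100000L)) {
    p2 <- as.numeric(P %*% p)
    if (max(abs(p2 - p)) < tol) { p <- p2; break }
    p <- p2
  }
  structure(list(distributions = dist, t_half = t_half, limit = p,
                 home = home), class = "mv_markov")
}

#' @export
print.mv_markov <- function(x, ...) {
  cat("Markov chain over", ncol(x$distributions), "attractors,",
      nrow(x$distributions) - 1L, "steps\n")
  cat("  escape half-time (from attractor", x$home, "):",
      if (is.na(x$t_half)) "not reached" else x$t_half, "\n")
  cat("  limiting distribution:", paste(round(x$limit, 4), collapse = " "), "\n")
  invisible(x)
}
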