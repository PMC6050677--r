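# Independent oracles and small hand-built models used across the suite.

# Literal sum-over-subsets evaluation of the image: for each non-input node,
# y = sum over regulator subsets I of K[I] * prod(S_j, j in I) *
# prod(1 - S_j, j not in I). Exactly one term is non-zero per state.
image_oracle <- function(model, state) {
  net <- model$network
  s <- state[net$nodes$name]
  y <- s
  for (v in net$nodes$name[!net$nodes$is_input]) {
    regs <- net$regulators[[v]]
    ia <- net$interactions[net$interactions$target == v, ]
    ia <- ia[match(regs, ia$source), ]
    S <- step_activity(s[regs], ia$threshold, ia$sign)
    total <- 0L
    k <- model$parameters[[v]]
    for (mask in seq_len(2^length(regs)) - 1L) {
      inI <- bitwAnd(mask, 2^(seq_along(regs) - 1L)) > 0L
      key <- paste(sort(regs[inI]), collapse = ",")
      kval <- k[[match(key, names(k))]]
      total <- total + kval * prod(S[inI]) * prod(1L - S[!inI])
    }
    y[v] <- total
  }
  y
}

# Brute-force attractor detection by transitive closure: a vertex lies in a
# terminal SCC iff everything reachable from it reaches back; components are
# the mutual-reachability classes of such vertices.
oracle_attractors <- function(edges) {
  n <- length(edges)
  A <- matrix(FALSE, n, n)
  for (v in seq_len(n)) A[v, edges[[v]]] <- TRUE
  R <- A | diag(TRUE, n)
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  terminal <- vapply(seq_len(n), function(v) all(!R[v, ] | R[, v]), TRUE)
  comps <- list()
  seen <- logical(n)
  for (v in which(terminal)) {
    if (seen[v]) next
    members <- which(R[v, ] & R[, v])
    seen[members] <- TRUE
    kind <- if (length(members) == 1L &&
                (length(edges[[v]]) == 0L || all(edges[[v]] == v)))
      "stationary" else "cyclic"
    comps[[length(comps) + 1L]] <- list(vertices = sort(members), kind = kind)
  }
  comps[order(vapply(comps, function(c) min(c$vertices), 1L))]
}

# Brute-force elementary-cycle enumeration: try every vertex subset and every
# cyclic ordering of it, keep orderings whose consecutive edges all exist.
oracle_cycles <- function(net) {
  nm <- net$nodes$name
  n <- length(nm)
  has_edge <- function(s, t)
    any(net$interactions$source == s & net$interactions$target == t)
  found <- character()
  for (mask in seq_len(2^n) - 1L) {
    subset <- nm[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
    k <- length(subset)
    if (k == 0L) next
    if (k == 1L) {
      if (has_edge(subset, subset)) found <- c(found, subset)
      next
    }
    # fix the first element to count each rotation once, then canonicalize
    perms <- perms_of(subset[-1])
    for (p in perms) {
      cyc <- c(subset[1], p)
      ok <- all(vapply(seq_len(k), function(i)
        has_edge(cyc[i], cyc[if (i == k) 1L else i + 1L]), TRUE))
      if (ok) found <- c(found, canon_cycle(cyc))
    }
  }
  sort(unique(found))
}

perms_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in perms_of(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

# canonical rotation-invariant key of a node cycle (rotate to the
# alphabetically smallest node)
canon_cycle <- function(nodes) {
  k <- length(nodes)
  if (k == 1L) return(nodes)
  i0 <- which(nodes == min(nodes))[1L]
  paste(c(nodes[i0:k], nodes[seq_len(i0 - 1L)]), collapse = ">")
}

circuit_key <- function(ci) canon_cycle(ci$nodes)

# two binary nodes, A activates B, B inhibits A; the classic negative loop
two_node_negative_loop <- function() {
  net <- logical_network(
    nodes = data.frame(name = c("A", "B"), max_level = c(1L, 1L)),
    interactions = data.frame(source = c("A", "B"), target = c("B", "A"),
                              sign = c("+", "-"), threshold = c(1L, 1L)))
  logical_model(net, list(
    A = stats::setNames(c(0L, 1L), c("", "B")),
    B = stats::setNames(c(0L, 1L), c("", "A"))))
}

# one binary node with a positive self-loop: two stable fixed points
one_node_positive_loop <- function() {
  net <- logical_network(
    nodes = data.frame(name = "A", max_level = 1L),
    interactions = data.frame(source = "A", target = "A",
                              sign = "+", threshold = 1L))
  logical_model(net, list(A = stats::setNames(c(0L, 1L), c("", "A"))))
}

# x-space transition pairs (from-label, to-label) of an STG
transition_pairs <- function(stg) {
  labs <- state_label(stg$states)
  out <- character()
  for (v in seq_along(stg$edges))
    for (w in stg$edges[[v]])
      if (labs[v] != labs[w]) out <- c(out, paste(labs[v], labs[w]))
  sort(unique(out))
}

hpa_inputs0 <- function(model) {
  nm <- model$network$nodes$name[model$network$nodes$is_input]
  if (!length(nm)) return(NULL)
  as.list(stats::setNames(rep(0L, length(nm)), nm))
}
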