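# Internal compiled form of a model: per-node integer tables so that image
# computation over whole state spaces is plain indexing.
#
# For node i with regulators r_1 < ... < r_k (alphabetical), the context of a
# state is encoded as a bitmask (bit j set iff the interaction from r_j is
# active); K values are stored as a vector indexed by bitmask + 1.

compile_model <- function(model) {
  if (!is.null(model$.compiled)) return(model$.compiled)
  net <- model$network
  nm <- net$nodes$name
  n <- length(nm)
  rho <- stats::setNames(net$nodes$max_level, nm)
  is_input <- stats::setNames(net$nodes$is_input, nm)

  reg_idx <- vector("list", n)   # regulator node indices (alphabetical order)
  reg_thr <- vector("list", n)
  reg_act <- vector("list", n)   # TRUE for "+", FALSE for "-"
  kvec <- vector("list", n)      # K by bitmask + 1
  for (i in seq_len(n)) {
    v <- nm[i]
    if (is_input[[v]]) next
    regs <- net$regulators[[v]]
    ia <- net$interactions[net$interactions$target == v, ]
    ia <- ia[match(regs, ia$source), ]
    reg_idx[[i]] <- match(regs, nm)
    reg_thr[[i]] <- ia$threshold
    reg_act[[i]] <- ia$sign == "+"
    keys <- vapply(all_subsets(regs), context_key, "")
    k <- model$parameters[[v]]
    # match() rather than name indexing: the basal key is the empty string,
    # which `[` would silently miss
    kvec[[i]] <- unname(k[match(keys, names(k))])
  }
  list(names = nm, n = n, rho = unname(rho), is_input = unname(is_input),
       reg_idx = reg_idx, reg_thr = reg_thr, reg_act = reg_act, kvec = kvec,
       delays = unname(model$delays[nm]))
}

# context bitmask of one node in one state (state: plain integer vector)
context_mask <- function(cm, state, i) {
  ri <- cm$reg_idx[[i]]
  if (!length(ri)) return(0L)
  lev <- state[ri]
  act <- ifelse(cm$reg_act[[i]], lev >= cm$reg_thr[[i]], lev < cm$reg_thr[[i]])
  sum(2L^(seq_along(ri) - 1L) * act)
}

image_compiled <- function(cm, state) {
  y <- state
  for (i in seq_len(cm$n)) {
    if (cm$is_input[i]) next
    y[i] <- cm$kvec[[i]][context_mask(cm, state, i) + 1L]
  }
  y
}

# Enumerate the full state space for a fixed input assignment.
# Returns S: n_states x n integer matrix (columns in node order), plus the
# mixed radix used for indexing (row i <-> index i).
enumerate_states <- function(model, inputs = NULL) {
  cm <- compile_model(model)
  nm <- cm$names
  lev <- lapply(seq_len(cm$n), function(i) {
    if (cm$is_input[i]) {
      if (is.null(inputs) || is.null(inputs[[nm[i]]]))
        stop("no level given for input node ", nm[i])
      as.integer(inputs[[nm[i]]])
    } else 0:cm$rho[i]
  })
  grid <- do.call(expand.grid, c(rev(lev), KEEP.OUT.ATTRS = FALSE))
  S <- as.matrix(grid[, rev(seq_len(cm$n)), drop = FALSE])
  dimnames(S) <- list(NULL, nm)
  storage.mode(S) <- "integer"
  S
}

# image matrix for every row of a state matrix
image_matrix <- function(model, S) {
  cm <- compile_model(model)
  Y <- S
  for (i in seq_len(cm$n)) {
    if (cm$is_input[i]) next
    ri <- cm$reg_idx[[i]]
    if (!length(ri)) { Y[, i] <- cm$kvec[[i]][1L]; next }
    mask <- integer(nrow(S))
    for (j in seq_along(ri)) {
      lev <- S[, ri[j]]
      act <- if (cm$reg_act[[i]][j]) lev >= cm$reg_thr[[i]][j] else lev < cm$reg_thr[[i]][j]
      mask <- mask + 2L^(j - 1L) * act
    }
    Y[, i] <- cm$kvec[[i]][mask + 1L]
  }
  Y
}
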