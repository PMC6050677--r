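#' Construct a signed, thresholded multi-valued regulatory network
#'
#' A regulatory network is a signed, weighted, directed graph. Each node `v`
#' takes discrete levels `0..max_level(v)`; each interaction `j -> i` carries a
#' sign (`"+"` activation, `"-"` inhibition) and an integer threshold
#' `theta` with `1 <= theta <= max_level(j)` above (for activators) or below
#' (for inhibitors) which the interaction context is active. Nodes with no
#' incoming interaction are *inputs*: they have no image and their level is
#' held constant by every update scheme.
#'
#' @param nodes data frame with columns `name` (unique identifiers) and
#'   `max_level` (integer >= 1; binary nodes have `max_level = 1`).
#' @param interactions data frame with columns `source`, `target`,
#'   `sign` (`"+"` or `"-"`) and `threshold`. At most one interaction per
#'   ordered (source, target) pair.
#' @return An object of class `mv_network`: a list with elements `nodes`
#'   (data frame `name`, `max_level`, `is_input`), `interactions`, and
#'   `regulators` (per non-input node, its regulator names in alphabetical
#'   order, the order used for context bitmasks).
#' @examples
#' net <- logical_network(
#'   nodes = data.frame(name = c("A", "B"), max_level = c(1, 1)),
#'   interactions = data.frame(source = c("A", "B"), target = c("B", "A"),
#'                             sign = c("+", "-"), threshold = c(1, 1))
#' )
#' @export
logical_network <- function(nodes, interactions) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "max_level") %in% names(nodes)))
  nodes$name <- as.character(nodes$name)
  nodes$max_level <- as.integer(nodes$max_level)
  if (anyDuplicated(nodes$name))
    stop("node names must be unique")
  if (any(nodes$max_level < 1L))
    stop("max_level must be >= 1 for every node")

  if (is.null(interactions) || nrow(as.data.frame(interactions)) == 0L) {
    interactions <- data.frame(source = character(), target = character(),
                               sign = character(), threshold = integer(),
                               stringsAsFactors = FALSE)
  } else {
    interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
    stopifnot(all(c("source", "target", "sign", "threshold") %in% names(interactions)))
    interactions$source <- as.character(interactions$source)
    interactions$target <- as.character(interactions$target)
    interactions$sign <- as.character(interactions$sign)
    interactions$threshold <- as.integer(interactions$threshold)
  }

  bad <- setdiff(c(interactions$source, interactions$target), nodes$name)
  if (length(bad))
    stop("interaction endpoint(s) not in node list: ", paste(bad, collapse = ", "))
  if (!all(interactions$sign %in% c("+", "-")))
    stop('interaction sign must be "+" or "-"')
  if (anyDuplicated(interactions[c("source", "target")]))
    stop("at most one interaction per ordered (source, target) pair")
  rho_src <- nodes$max_level[match(interactions$source, nodes$name)]
  if (any(interactions$threshold < 1L | interactions$threshold > rho_src))
    stop("interaction threshold must lie in 1..max_level(source)")

  nodes$is_input <- !(nodes$name %in% interactions$target)
  regulators <- lapply(nodes$name, function(v) {
    if (!(v %in% interactions$target)) return(character())
    sort(interactions$source[interactions$target == v])
  })
  names(regulators) <- nodes$name

  structure(list(nodes = nodes, interactions = interactions,
                 regulators = regulators),
            class = "mv_network")
}

#' @export
print.mv_network <- function(x, ...) {
  cat("Multi-valued regulatory network:", nrow(x$nodes), "nodes,",
      nrow(x$interactions), "interactions\n")
  lv <- paste0(x$nodes$name, " (0..", x$nodes$max_level,
               ifelse(x$nodes$is_input, ", input", ""), ")")
  cat("  ", paste(lv, collapse = ", "), "\n", sep = "")
  if (nrow(x$interactions)) {
    arrows <- ifelse(x$interactions$sign == "+", " -> ", " -| ")
    cat("  ", paste0(x$interactions$source, arrows, x$interactions$target,
                     " [theta=", x$interactions$threshold, "]", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# canonical context key: regulator names sorted alphabetically, comma-joined;
# the basal (empty) context has key ""
context_key <- function(regs) paste(sort(regs), collapse = ",")

#' Bundle a network with its logical parameterization and update configuration
#'
#' The logical parameterization assigns to every non-input node `i` and every
#' subset `I` of its regulators a target level `K[i, I]` in `0..max_level(i)`:
#' the level node `i` tends toward when exactly the regulator contexts in `I`
#' are active. All `2^r` subsets must be given explicitly (the empty subset is
#' the basal value).
#'
#' @param network an [logical_network()] object.
#' @param parameters named list, one element per non-input node; each element
#'   a named integer vector mapping context keys to K values. A context key is
#'   the alphabetically sorted, comma-separated regulator names (`""` for the
#'   basal context), e.g. `setNames(c(0, 1, 1, 1), c("", "CRH", "CRH,R", "R"))`.
#' @param delays optional named integer vector of per-node update delays
#'   `d >= 1` for the priority-with-memory scheme; missing non-input nodes
#'   default to 1 (with a warning when `delays` is partially specified).
#' @return An object of class `mv_model`.
#' @export
logical_model <- function(network, parameters, delays = NULL) {
  stopifnot(inherits(network, "mv_network"))
  non_input <- network$nodes$name[!network$nodes$is_input]
  parameters <- lapply(parameters, function(k) {
    k2 <- as.integer(k); names(k2) <- names(k); k2
  })

  all_nodes <- network$nodes$name
  d <- stats::setNames(rep(1L, length(all_nodes)), all_nodes)
  if (!is.null(delays)) {
    unknown <- setdiff(names(delays), all_nodes)
    if (length(unknown)) stop("delays given for unknown node(s): ",
                              paste(unknown, collapse = ", "))
    if (any(delays < 1)) stop("delays must be >= 1")
    missing_d <- setdiff(non_input, names(delays))
    if (length(missing_d))
      warning("no delay given for ", paste(missing_d, collapse = ", "),
              "; defaulting to 1")
    d[names(delays)] <- as.integer(delays)
  }

  m <- structure(list(network = network, parameters = parameters, delays = d),
                 class = "mv_model")
  rep <- validate_model(m)
  if (length(rep)) stop("invalid model:\n  ", paste(rep, collapse = "\n  "))
  m
}

#' @export
print.mv_model <- function(x, ...) {
  print(x$network)
  cat("K parameters:\n")
  for (v in names(x$parameters)) {
    k <- x$parameters[[v]]
    ctx <- ifelse(names(k) == "", "{}", paste0("{", names(k), "}"))
    cat("  ", v, ": ", paste0("K", ctx, "=", k, collapse = ", "), "\n", sep = "")
  }
  if (any(x$delays != 1L))
    cat("priority delays: ",
        paste0(names(x$delays), "=", x$delays, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Validate a model against the type invariants
#'
#' Checks node/interaction invariants, completeness of the K table (one entry
#' per regulator subset of every non-input node, including the basal context)
#' and the bound `0 <= K <= max_level(target)`.
#'
#' @param model an `mv_model`, or a list with elements `network`,
#'   `parameters` and optionally `delays` not yet blessed.
#' @return character vector of violations; `character(0)` if the model is valid.
#' @export
validate_model <- function(model) {
  net <- model$network
  pars <- model$parameters
  out <- character()
  non_input <- net$nodes$name[!net$nodes$is_input]
  for (v in non_input) {
    regs <- net$regulators[[v]]
    want <- vapply(all_subsets(regs), context_key, "")
    k <- pars[[v]]
    if (is.null(k)) {
      out <- c(out, sprintf("node %s: no K entries", v))
      next
    }
    miss <- setdiff(want, names(k))
    if (length(miss))
      out <- c(out, sprintf("node %s: missing K entry for context {%s}",
                            v, miss))
    extra <- setdiff(names(k), want)
    if (length(extra))
      out <- c(out, sprintf("node %s: K entry for unknown context {%s}",
                            v, extra))
    rho <- net$nodes$max_level[net$nodes$name == v]
    bad <- k[!is.na(k) & (k < 0L | k > rho)]
    if (length(bad))
      out <- c(out, sprintf("node %s: K value %d outside 0..%d", v, bad, rho))
  }
  extra_nodes <- setdiff(names(pars), non_input)
  if (length(extra_nodes))
    out <- c(out, sprintf("K entries given for input or unknown node %s",
                          extra_nodes))
  if (!is.null(model$delays) && any(model$delays < 1L))
    out <- c(out, "delays must be >= 1")
  out
}

# all subsets of a character vector, as a list (first element: empty set)
all_subsets <- function(x) {
  n <- length(x)
  lapply(seq_len(2^n) - 1L, function(mask) x[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L])
}

#' Interaction activity step function
#'
#' Returns 1 when the interaction context is active: for an activator, when
#' the source level is at or above the threshold; for an inhibitor, when the
#' source level is below the threshold (absent inhibitor = active inhibitory
#' context).
#'
#' @param level integer source level (>= 0).
#' @param threshold integer interaction threshold (>= 1).
#' @param sign `"+"` or `"-"`.
#' @return 0 or 1 (vectorized over the arguments).
#' @export
step_activity <- function(level, threshold, sign) {
  stopifnot(all(level >= 0), all(threshold >= 1), all(sign %in% c("+", "-")))
  as.integer(ifelse(sign == "+", level >= threshold, level < threshold))
}

#' Active regulator subset of a node in a state
#'
#' @param model an `mv_model` (or `mv_network`).
#' @param state named or node-ordered integer vector of levels.
#' @param target a non-input node name.
#' @return character vector of regulators whose interaction context is active
#'   (alphabetical order); this is the subset `I` indexing the K table.
#' @export
active_regulators <- function(model, state, target) {
  net <- if (inherits(model, "mv_network")) model else model$network
  if (!(target %in% net$nodes$name)) stop("unknown node: ", target)
  if (net$nodes$is_input[net$nodes$name == target])
    stop("node ", target, " is an input and has no regulators")
  state <- as_state(net, state)
  regs <- net$regulators[[target]]
  ia <- net$interactions[net$interactions$target == target, ]
  ia <- ia[match(regs, ia$source), ]
  regs[step_activity(state[regs], ia$threshold, ia$sign) == 1L]
}

# coerce a state to the canonical named integer vector in node order
as_state <- function(net, state) {
  nm <- net$nodes$name
  if (!is.null(names(state))) {
    miss <- setdiff(nm, names(state))
    if (length(miss)) stop("state missing node(s): ", paste(miss, collapse = ", "))
    state <- state[nm]
  } else if (length(state) != length(nm)) {
    stop("state must have one level per node")
  }
  state <- stats::setNames(as.integer(state), nm)
  if (any(state < 0L | state > net$nodes$max_level))
    stop("state level outside 0..max_level")
  state
}

#' Image of a state: the vector of target levels
#'
#' For each non-input node the image is the K parameter of its unique active
#' regulator subset; input nodes are their own image.
#'
#' @inheritParams active_regulators
#' @return named integer vector of image levels.
#' @export
state_image <- function(model, state) {
  stopifnot(inherits(model, "mv_model"))
  cm <- compile_model(model)
  s <- as_state(model$network, state)
  image_compiled(cm, s)
}
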