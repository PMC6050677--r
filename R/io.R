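#' Write a model to a YAML or JSON schema file
#'
#' The schema has four top-level keys: `nodes` (name, max_level, input),
#' `interactions` (source, target, sign, threshold), `parameters` (per
#' target node, a list of `{context, K}` entries where `context` is the
#' sorted list of active regulators) and `update` (scheme and per-node
#' delays). Loading and saving round-trips losslessly.
#'
#' @param model an `mv_model`.
#' @param path output file; the extension selects the format (`.yaml`/`.yml`
#'   or `.json`).
#' @param scheme update scheme recorded in the file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, scheme = "priority") {
  net <- model$network
  doc <- list(
    nodes = lapply(seq_len(nrow(net$nodes)), function(i)
      list(name = net$nodes$name[i],
           max_level = net$nodes$max_level[i],
           input = net$nodes$is_input[i])),
    interactions = lapply(seq_len(nrow(net$interactions)), function(i)
      list(source = net$interactions$source[i],
           target = net$interactions$target[i],
           sign = net$interactions$sign[i],
           threshold = net$interactions$threshold[i])),
    parameters = lapply(model$parameters, function(k)
      lapply(seq_along(k), function(s)
        list(context = as.list(if (nzchar(names(k)[s]))
               strsplit(names(k)[s], ",")[[1]] else character()),
             K = unname(k[s])))),
    update = list(scheme = scheme, delays = as.list(model$delays)))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  } else stop("unknown model file extension: ", path)
  invisible(path)
}

#' Read a model from a YAML or JSON schema file
#'
#' @param path schema file written by [write_model()] (or authored by hand).
#' @return an `mv_model`; schema violations are reported with the offending
#'   node/context named.
#' @export
read_model <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path)
  } else stop("unknown model file extension: ", path)
  for (key in c("nodes", "interactions", "parameters"))
    if (is.null(doc[[key]])) stop("model file missing key: ", key)
  nodes <- data.frame(
    name = vapply(doc$nodes, function(x) as.character(x$name), ""),
    max_level = vapply(doc$nodes, function(x) as.integer(x$max_level), 0L))
  ias <- if (length(doc$interactions)) data.frame(
    source = vapply(doc$interactions, function(x) as.character(x$source), ""),
    target = vapply(doc$interactions, function(x) as.character(x$target), ""),
    sign = vapply(doc$interactions, function(x) as.character(x$sign), ""),
    threshold = vapply(doc$interactions, function(x) as.integer(x$threshold), 0L))
  else NULL
  net <- logical_network(nodes, ias)
  params <- lapply(doc$parameters, function(entries) {
    k <- integer(0)
    for (e in entries) {
      if (is.null(e$K)) stop("parameter entry without K value")
      k[[context_key(unlist(e$context))]] <- as.integer(e$K)
    }
    k
  })
  delays <- NULL
  if (!is.null(doc$update$delays)) {
    delays <- unlist(doc$update$delays)
    missing_d <- setdiff(net$nodes$name[!net$nodes$is_input], names(delays))
    if (length(missing_d))
      warning("no delay for ", paste(missing_d, collapse = ", "),
              "; defaulting to 1")
  }
  m <- logical_model(net, params, delays = delays)
  attr(m, "scheme") <- doc$update$scheme
  m
}

#' Export a state transition graph to DOT or GraphML
#'
#' Vertices are labeled with the bracket state notation (for
#' memory-extended graphs, the level-space projection); when an attractor
#' report is supplied, attractor vertices carry their attractor id as an
#' attribute (`attractor` in GraphML, a `color`-coded `attractor` attribute
#' in DOT), partitioning the terminal components.
#'
#' @param stg an `mv_stg`.
#' @param path output file.
#' @param format `"dot"` or `"graphml"`.
#' @param attractors optional [find_attractors()] result used to tag
#'   attractor vertices.
#' @return `path`, invisibly.
#' @export
export_stg <- function(stg, path, format = c("dot", "graphml"),
                       attractors = NULL) {
  format <- match.arg(format)
  n <- nrow(stg$states)
  labels <- state_label(stg$states)
  tag <- integer(n)
  if (!is.null(attractors))
    for (a in attractors) tag[a$vertices] <- a$id
  if (format == "dot") {
    lines <- c("digraph stg {")
    for (v in seq_len(n)) {
      attr_txt <- sprintf("label=\"%s\"", labels[v])
      if (tag[v] > 0L)
        attr_txt <- paste0(attr_txt, sprintf(", attractor=%d, style=filled", tag[v]))
      lines <- c(lines, sprintf("  v%d [%s];", v, attr_txt))
    }
    for (v in seq_len(n)) for (w in stg$edges[[v]])
      lines <- c(lines, sprintf("  v%d -> v%d;", v, w))
    lines <- c(lines, "}")
    writeLines(lines, path)
  } else {
    esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
    lines <- c(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
      "  <key id=\"d0\" for=\"node\" attr.name=\"label\" attr.type=\"string\"/>",
      "  <key id=\"d1\" for=\"node\" attr.name=\"attractor\" attr.type=\"int\"/>",
      "  <graph id=\"stg\" edgedefault=\"directed\">")
    for (v in seq_len(n))
      lines <- c(lines, sprintf(
        "    <node id=\"v%d\"><data key=\"d0\">%s</data><data key=\"d1\">%d</data></node>",
        v, esc(labels[v]), tag[v]))
    e <- 0L
    for (v in seq_len(n)) for (w in stg$edges[[v]]) {
      e <- e + 1L
      lines <- c(lines, sprintf(
        "    <edge id=\"e%d\" source=\"v%d\" target=\"v%d\"/>", e, v, w))
    }
    lines <- c(lines, "  </graph>", "</graphml>")
    writeLines(lines, path)
  }
  invisible(path)
}
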