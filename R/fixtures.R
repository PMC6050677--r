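#' HPA axis model at rest
#'
#' Four-variable model of the hypothalamic-pituitary-adrenal axis:
#' CRH (0-1) stimulates ACTH (0-1), ACTH stimulates cortisol CORT (0-2),
#' CORT feeds back negatively on CRH and up-regulates the glucocorticoid
#' receptor R (0-2), which inhibits ACTH and sustains its own expression.
#' CORT's two outputs carry thresholds 1 (to CRH) and 2 (to R); R's two
#' outputs carry thresholds 1 (to ACTH) and 2 (self-loop). The K table is
#' the unique parameterization supporting two cyclic attractors, and the
#' priority-with-memory delays place CRH, ACTH and R in the fast class
#' (d = 1) and the peripherally released CORT in the slow class (d = 4).
#'
#' @return an `mv_model`.
#' @export
hpa_resting_model <- function() {
  net <- logical_network(
    nodes = data.frame(name = c("CRH", "ACTH", "CORT", "R"),
                       max_level = c(1L, 1L, 2L, 2L)),
    interactions = data.frame(
      source = c("CORT", "CRH", "R", "ACTH", "CORT", "R"),
      target = c("CRH", "ACTH", "ACTH", "CORT", "R", "R"),
      sign = c("-", "+", "-", "+", "+", "+"),
      threshold = c(1L, 1L, 1L, 1L, 2L, 2L)))
  params <- list(
    CRH  = stats::setNames(c(0L, 1L), c("", "CORT")),
    ACTH = stats::setNames(c(0L, 1L, 1L, 1L), c("", "CRH", "CRH,R", "R")),
    CORT = stats::setNames(c(0L, 2L), c("", "ACTH")),
    R    = stats::setNames(c(0L, 1L, 2L, 2L), c("", "CORT", "CORT,R", "R")))
  logical_model(net, params,
                delays = c(CRH = 1L, ACTH = 1L, CORT = 4L, R = 1L))
}

#' HPA axis model under an external stressor
#'
#' Adds an input node `Stress` (0-1) with an activating edge onto CRH
#' (threshold 1). The four CRH context parameters are not guessed: they are
#' recovered by running [calibrate_input()] on the resting model and
#' retaining, per the calibration criteria, the sets that (i) reproduce the
#' resting attractor report when stress is absent and (ii) under persistent
#' stress support stationary states overlapping both resting attractors.
#' `tone = "normal"` selects the retained set that preserves a cyclic
#' attractor under stress; `tone = "heightened"` the set whose attractor
#' space collapses to stationary points only.
#'
#' @param tone `"normal"` or `"heightened"` stress sensitivity.
#' @return an `mv_model` (with attribute `"calibration"`, the full
#'   [calibrate_input()] result).
#' @export
hpa_stress_model <- function(tone = c("normal", "heightened")) {
  tone <- match.arg(tone)
  cal <- hpa_stress_calibration()
  k_crh <- cal$retained_params[[tone]]
  m <- stress_model_with(k_crh)
  attr(m, "calibration") <- cal
  m
}

# resting model + Stress input with a given CRH K table
stress_model_with <- function(k_crh) {
  rest <- hpa_resting_model()
  net <- logical_network(
    nodes = rbind(rest$network$nodes[c("name", "max_level")],
                  data.frame(name = "Stress", max_level = 1L)),
    interactions = rbind(rest$network$interactions,
                         data.frame(source = "Stress", target = "CRH",
                                    sign = "+", threshold = 1L)))
  params <- rest$parameters
  params$CRH <- k_crh
  logical_model(net, params, delays = c(rest$delays, Stress = 1L))
}

# memoized stress calibration (computed once per session)
fixture_cache <- new.env(parent = emptyenv())
hpa_stress_calibration <- function() {
  if (is.null(fixture_cache$stress_cal))
    fixture_cache$stress_cal <- calibrate_input(hpa_resting_model(), "Stress",
                                                scheme = "priority",
                                                target = "CRH")
  fixture_cache$stress_cal
}

#' HPA axis model under glucocorticoid-receptor blockade
#'
#' Adds an input node `Drug` (0-1) with an inhibitory edge onto R
#' (threshold 1). In drug-active contexts R's K values are capped at level 1,
#' an idealized blockade of receptor saturation: the self-sustaining R = 2
#' context is destroyed while the healthy cycle, which never requires R = 2,
#' is untouched. With `Drug = 0` the model reduces exactly to the resting
#' model.
#'
#' @return an `mv_model`.
#' @export
hpa_drug_model <- function() {
  rest <- hpa_resting_model()
  net <- logical_network(
    nodes = rbind(rest$network$nodes[c("name", "max_level")],
                  data.frame(name = "Drug", max_level = 1L)),
    interactions = rbind(rest$network$interactions,
                         data.frame(source = "Drug", target = "R",
                                    sign = "-", threshold = 1L)))
  params <- rest$parameters
  # R's regulators are now CORT, Drug, R (alphabetical); the inhibitory Drug
  # context is active (Drug in I) when the drug is ABSENT, so contexts
  # without "Drug" are the drug-exposed ones and get capped at 1
  base <- rest$parameters$R   # contexts over {CORT, R}
  k_r <- integer(0)
  for (s in seq_along(base)) {
    ctx <- names(base)[s]
    with_drug_absent <- context_key(c(if (nzchar(ctx)) strsplit(ctx, ",")[[1]], "Drug"))
    k_r[[with_drug_absent]] <- base[[s]]
    k_r[[ctx]] <- min(base[[s]], 1L)
  }
  params$R <- k_r
  logical_model(net, params, delays = c(rest$delays, Drug = 1L))
}

#' Random multi-valued network generator for property tests
#'
#' Draws a reproducible random signed, thresholded network with a complete
#' random K table: each ordered node pair receives an interaction with
#' probability `edge_density`, with a uniform sign and a uniform threshold in
#' `1..max_level(source)`; every K entry is uniform in `0..max_level(target)`.
#' Nodes left without regulators become inputs.
#'
#' @param n_nodes number of nodes (small; state spaces are exhaustive).
#' @param max_level maximum level of every node.
#' @param edge_density probability of each directed edge, in (0, 1].
#' @param seed integer seed.
#' @param delays optional delays; defaults to 1 for all nodes.
#' @return an `mv_model`.
#' @export
random_model <- function(n_nodes = 3, max_level = 2, edge_density = 0.5,
                         seed = 1, delays = NULL) {
  if (edge_density <= 0 || edge_density > 1)
    stop("edge_density must be in (0, 1]")
  set.seed(seed)
  nm <- paste0("n", seq_len(n_nodes))
  pairs <- expand.grid(source = nm, target = nm, stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(pairs)) < edge_density
  ia <- pairs[keep, , drop = FALSE]
  if (nrow(ia)) {
    ia$sign <- sample(c("+", "-"), nrow(ia), replace = TRUE)
    ia$threshold <- vapply(seq_len(nrow(ia)), function(k)
      sample.int(max_level, 1L), integer(1))
  } else {
    ia <- NULL
  }
  net <- logical_network(
    nodes = data.frame(name = nm, max_level = rep(max_level, n_nodes)), ia)
  params <- list()
  for (v in nm[!net$nodes$is_input]) {
    regs <- net$regulators[[v]]
    keys <- vapply(all_subsets(regs), context_key, "")
    params[[v]] <- stats::setNames(
      sample(0:max_level, length(keys), replace = TRUE), keys)
  }
  logical_model(net, params, delays = delays)
}
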