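# Transient-perturbation analysis of cell-type plasticity.
#
# A transient perturbation flips one node of an attractor state for exactly
# one synchronous step; afterwards the node obeys its rule again. For
# extrinsic inputs under a clamped micro-environment the clamp is suspended
# for that one step and then restored, so an input flip models a temporary
# change of the micro-environment. A perturbation whose trajectory ends in
# an attractor of a different phenotype class is a transition (plasticity);
# return to the original class is stability. Transition identity is judged
# at the class level: a jump to a different attractor of the same class
# counts as a self-loop.

node_category_vec <- function(net) {
  stats::setNames(ifelse(net$nodes %in% net$inputs, "extrinsic", "intrinsic"),
                  net$nodes)
}

#' Transiently perturb one node of an attractor
#'
#' @param net A `logic_network`.
#' @param attractor An attractor (list with `states` matrix); for cyclic
#'   attractors the canonical first state is perturbed.
#' @param node Node to flip.
#' @param env `environment_spec` the attractor lives under (or `NULL` for a
#'   free network).
#' @param rules Phenotype rules for labeling source and outcome.
#' @param direction Optional `"activation"`/`"inhibition"`; supplying the
#'   direction that matches the node's current value is refused (flipping a
#'   node to its own value is not a perturbation).
#' @return List (class `perturbation_event`): `node`, `direction`,
#'   `source_label`, `outcome_label`, `outcome_attractor`, `is_transition`.
#' @export
transient_perturb <- function(net, attractor, node, env = NULL,
                              rules = phenotype_rules(), direction = NULL) {
  if (!node %in% net$nodes) abort2("unknown node '", node, "'")
  state <- attractor$states[1L, ]
  cur <- state[[node]]
  dir <- if (cur == 1L) "inhibition" else "activation"
  if (!is.null(direction) && direction != dir)
    abort2("perturbing '", node, "' to its current value is not a perturbation")
  clamped <- if (is.null(env)) integer(0) else env$clamped
  pert <- state
  pert[node] <- 1L - cur
  nxt <- synchronous_step(net, pert)   # inputs follow identity: clamp suspended
  nxt[names(clamped)] <- clamped       # clamp restored
  res <- find_attractor(net, nxt, clamp = clamped)
  src_label <- classify_attractor(attractor, rules)
  out_label <- classify_attractor(res$attractor, rules)
  structure(list(node = node, direction = dir, source_label = src_label,
                 outcome_label = out_label, outcome_attractor = res$attractor,
                 is_transition = !identical(src_label, out_label)),
            class = "perturbation_event")
}

# Vectorized per-environment scan used by all aggregate statistics.
scan_one_environment <- function(net, env, rules) {
  sm <- successor_map(net, env$clamped)
  dec <- decompose_successor(sm$succ)
  atts <- lapply(seq_along(dec$cycles), function(i) {
    codes <- dec$cycles[[i]]
    rot <- canonical_rotation(codes, sm$free, sm$clamp, net$nodes)
    codes <- c(codes[rot:length(codes)], codes[seq_len(rot - 1L)])
    list(states = decode_states(codes, sm$free, sm$clamp, net$nodes),
         period = length(codes), basin_size = dec$basin[i])
  })
  labels <- vapply(atts, classify_attractor, character(1), rules = rules)
  cat_vec <- node_category_vec(net)
  ev <- list(); n <- 0L
  for (ai in seq_along(atts)) {
    state <- atts[[ai]]$states[1L, ]
    for (nd in net$nodes) {
      cur <- state[[nd]]
      pert <- state
      pert[nd] <- 1L - cur
      nxt <- synchronous_step(net, pert)
      nxt[names(sm$clamp)] <- sm$clamp
      code <- encode_state(nxt, sm$free)
      out_ai <- dec$label[code + 1L]
      n <- n + 1L
      ev[[n]] <- data.frame(
        environment = env$name,
        source_attractor = ai, source_label = labels[ai],
        node = nd, category = unname(cat_vec[nd]),
        direction = if (cur == 1L) "inhibition" else "activation",
        outcome_attractor = out_ai, outcome_label = labels[out_ai],
        stringsAsFactors = FALSE)
    }
  }
  events <- do.call(rbind, ev)
  events$is_transition <- events$source_label != events$outcome_label
  basins <- vapply(atts, function(a) a$basin_size, numeric(1))
  list(events = events, labels = labels, basins = basins)
}

#' Perturb every (attractor, node) pair across micro-environments
#'
#' @param net A `logic_network`.
#' @param environments List of `environment_spec`s; default all `2^k` fully
#'   specified extrinsic assignments.
#' @param rules Phenotype rules.
#' @return List of class `perturbation_scan`: `events` (one row per
#'   perturbation), `class_basins` (basin size per environment and label).
#' @export
perturbation_scan <- function(net, environments = NULL,
                              rules = phenotype_rules()) {
  if (is.null(environments)) environments <- all_environments(net)
  evs <- list(); cb <- list()
  for (i in seq_along(environments)) {
    one <- scan_one_environment(net, environments[[i]], rules)
    evs[[i]] <- one$events
    agg <- tapply(one$basins, one$labels, sum)
    cb[[i]] <- data.frame(environment = environments[[i]]$name,
                          label = names(agg), basin = as.integer(agg),
                          row.names = NULL)
  }
  structure(list(events = do.call(rbind, evs),
                 class_basins = do.call(rbind, cb)),
            class = "perturbation_scan")
}

#' Build a cell-fate map from a perturbation scan
#'
#' Nodes are phenotype classes (weighted by total basin size); edges count
#' class-to-class transitions; self-loops count perturbations that returned
#' to the original class. Edge counts plus self-loop counts equal the total
#' number of perturbations in scope.
#'
#' @param scan A `perturbation_scan` (or its events for one environment).
#' @return List of class `fate_map`: `nodes` (label, basin), `edges`
#'   (from, to, count; from != to), `self_loops` (label, count).
#' @export
build_fate_map <- function(scan) {
  events <- if (inherits(scan, "perturbation_scan")) scan$events else scan
  basins <- if (inherits(scan, "perturbation_scan")) {
    agg <- tapply(scan$class_basins$basin, scan$class_basins$label, sum)
    data.frame(label = names(agg), basin = as.integer(agg), row.names = NULL)
  } else NULL
  trans <- events[events$is_transition, , drop = FALSE]
  selfs <- events[!events$is_transition, , drop = FALSE]
  ek <- paste(trans$source_label, trans$outcome_label, sep = " -> ")
  et <- table(ek)
  edges <- if (length(et)) {
    parts <- strsplit(names(et), " -> ", fixed = TRUE)
    data.frame(from = vapply(parts, `[`, "", 1),
               to = vapply(parts, `[`, "", 2),
               count = as.integer(et), row.names = NULL)
  } else data.frame(from = character(0), to = character(0), count = integer(0))
  st <- table(selfs$source_label)
  self_loops <- data.frame(label = names(st), count = as.integer(st),
                           row.names = NULL)
  if (is.null(basins)) {
    labs <- sort(unique(c(events$source_label, events$outcome_label)))
    basins <- data.frame(label = labs, basin = NA_integer_)
  }
  structure(list(nodes = basins, edges = edges, self_loops = self_loops,
                 n_perturbations = nrow(events)), class = "fate_map")
}

#' Convert a fate map to an igraph graph
#'
#' Node attribute `basin_size`; edge attribute `count` (self-loops included
#' as loop edges). Useful for GraphML/DOT export via [export_fate_map()].
#' @param fm A `fate_map`.
#' @return An `igraph` object.
#' @export
fate_map_graph <- function(fm) {
  verts <- fm$nodes
  names(verts)[names(verts) == "label"] <- "name"
  names(verts)[names(verts) == "basin"] <- "basin_size"
  loops <- fm$self_loops
  edges <- rbind(fm$edges,
                 data.frame(from = loops$label, to = loops$label,
                            count = loops$count))
  extra <- setdiff(unique(c(edges$from, edges$to)), verts$name)
  if (length(extra))
    verts <- rbind(verts, data.frame(name = extra, basin_size = NA_integer_))
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = verts)
}

#' Export a fate map as GraphML and DOT
#'
#' @param fm A `fate_map`.
#' @param basename Output path without extension; writes
#'   `<basename>.graphml` and `<basename>.dot`.
#' @return Invisibly, the two file paths.
#' @export
export_fate_map <- function(fm, basename) {
  g <- fate_map_graph(fm)
  p1 <- paste0(basename, ".graphml")
  p2 <- paste0(basename, ".dot")
  igraph::write_graph(g, p1, format = "graphml")
  igraph::write_graph(g, p2, format = "dot")
  invisible(c(graphml = p1, dot = p2))
}

#' Transition statistics of a perturbation scan
#'
#' Micro-averaged proportions (transitions / perturbations) overall, split
#' by node category (intrinsic components vs extrinsic cytokines), per node
#' and per perturbation direction (activation 0->1 vs inhibition 1->0). A
#' macro-average (mean over per-attractor transition fractions) is also
#' reported since averaging conventions differ between studies.
#'
#' @param scan A `perturbation_scan` or an events data frame.
#' @param percent Report proportions as percentages.
#' @return List of class `transition_stats`.
#' @export
transition_statistics <- function(scan, percent = TRUE) {
  events <- if (inherits(scan, "perturbation_scan")) scan$events else scan
  if (!NROW(events)) abort2("empty event list")
  f <- if (percent) 100 else 1
  frac <- function(x) f * mean(x)
  per_node <- vapply(split(events$is_transition, events$node), frac, numeric(1))
  per_cat <- vapply(split(events$is_transition, events$category), frac, numeric(1))
  per_dir_n <- vapply(split(events$is_transition, events$direction), sum,
                      numeric(1))
  per_dir_f <- vapply(split(events$is_transition, events$direction), frac,
                      numeric(1))
  akey <- paste(events$environment, events$source_attractor)
  macro <- f * mean(vapply(split(events$is_transition, akey), mean, numeric(1)))
  structure(list(
    n_perturbations = nrow(events),
    n_transitions = sum(events$is_transition),
    overall_fraction = frac(events$is_transition),
    intrinsic_fraction = unname(per_cat["intrinsic"]),
    extrinsic_fraction = unname(per_cat["extrinsic"]),
    per_node_fraction = per_node,
    per_direction_transitions = per_dir_n,
    per_direction_fraction = per_dir_f,
    macro_average_fraction = macro,
    percent = percent), class = "transition_stats")
}

#' @export
print.transition_stats <- function(x, ...) {
  u <- if (x$percent) "%" else ""
  cat(sprintf("transition_stats: %d perturbations, %d transitions\n",
              x$n_perturbations, x$n_transitions))
  cat(sprintf("  overall %.2f%s | intrinsic %.2f%s | extrinsic %.2f%s | macro %.2f%s\n",
              x$overall_fraction, u, x$intrinsic_fraction, u,
              x$extrinsic_fraction, u, x$macro_average_fraction, u))
  invisible(x)
}

#' Census of realized class-to-class transitions
#'
#' Counts ordered phenotype-class pairs realized by at least one
#' perturbation event. `possible` is the square of the number of distinct
#' classes (self-pairs included, matching the convention that k classes
#' allow k^2 ordered transitions); observed cross-class pairs and realized
#' self-pairs are reported separately.
#'
#' @param scan A `perturbation_scan` or events data frame.
#' @return List: `classes`, `possible`, `observed_cross`, `observed_self`,
#'   `pairs` (data frame of realized from/to pairs).
#' @export
count_class_transitions <- function(scan) {
  events <- if (inherits(scan, "perturbation_scan")) scan$events else scan
  classes <- sort(unique(c(events$source_label, events$outcome_label)))
  pairs <- unique(events[, c("source_label", "outcome_label")])
  cross <- pairs[pairs$source_label != pairs$outcome_label, , drop = FALSE]
  selfp <- pairs[pairs$source_label == pairs$outcome_label, , drop = FALSE]
  list(classes = classes,
       possible = length(classes)^2,
       observed_cross = nrow(cross),
       observed_self = nrow(selfp),
       pairs = cross[order(cross$source_label, cross$outcome_label), ])
}

#' Per-class stability scores under an environment
#'
#' The stability of a class is the proportion of perturbations applied to
#' its attractors that return to the same class (1 minus its transition
#' fraction).
#'
#' @param net A `logic_network`.
#' @param env An `environment_spec`.
#' @param rules Phenotype rules.
#' @return Named numeric vector: label -> self-return proportion in `[0,1]`.
#' @export
stability_score <- function(net, env, rules = phenotype_rules()) {
  one <- scan_one_environment(net, env, rules)
  vapply(split(!one$events$is_transition, one$events$source_label), mean,
         numeric(1))
}
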