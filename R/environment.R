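# Micro-environments: clamped assignments of the extrinsic cytokine inputs.
#
# A named preset fixes the listed extrinsic cytokines at 1 and (by default)
# all others at 0, mirroring the contrast between polarizing conditions and
# the cytokine-free condition; set `free_unlisted = TRUE` to leave unlisted
# inputs free instead.

ENV_PRESETS <- list(
  Th0   = character(0),
  Th1   = "IFNGe",
  Th2   = c("IL4e", "IL2e"),
  Th17  = c("IL21e", "TGFBe"),
  iTreg = c("TGFBe", "IL2e"),
  IL10  = "IL10e",
  Tfh   = "IL21e",
  Th9   = c("IL4e", "TGFBe")
)

#' Construct a micro-environment
#'
#' @param net The network (its declared inputs are the clampable nodes).
#' @param preset Name of a polarizing preset (Th0, Th1, Th2, Th17, iTreg,
#'   IL10, Tfh, Th9), or `NULL` to give `clamped` directly.
#' @param clamped Named 0/1 vector over input nodes (used when `preset` is
#'   `NULL`); inputs omitted from it are left free.
#' @param free_unlisted For presets: leave unlisted extrinsic nodes free
#'   instead of clamping them to 0.
#' @return List of class `environment_spec` with `name` and `clamped`.
#' @export
make_environment <- function(net, preset = NULL, clamped = NULL,
                             free_unlisted = FALSE) {
  if (!is.null(preset)) {
    if (!preset %in% names(ENV_PRESETS))
      abort2("unknown environment preset '", preset, "'")
    on <- ENV_PRESETS[[preset]]
    miss <- setdiff(on, net$inputs)
    if (length(miss))
      abort2("preset '", preset, "' needs input(s) absent from the network: ",
             paste(miss, collapse = ", "))
    clamped <- if (free_unlisted)
      stats::setNames(rep(1L, length(on)), on)
    else
      stats::setNames(as.integer(net$inputs %in% on), net$inputs)
    name <- preset
  } else {
    clamped <- stats::setNames(as.integer(clamped), names(clamped))
    name <- if (any(clamped == 1L))
      paste(names(clamped)[clamped == 1L], collapse = "+") else "none"
  }
  bad <- setdiff(names(clamped), net$inputs)
  if (length(bad))
    abort2("environment clamps non-input node(s): ",
           paste(bad, collapse = ", "), " (that is a mutant, not an environment)")
  structure(list(name = name, clamped = clamped), class = "environment_spec")
}

#' All fully specified micro-environments of a network
#'
#' @param net A `logic_network` with `k` inputs.
#' @return List of `2^k` `environment_spec` objects, one per assignment of
#'   the extrinsic cytokines.
#' @export
all_environments <- function(net) {
  ins <- net$inputs
  k <- length(ins)
  lapply(0:(2L^k - 1L), function(code) {
    clamped <- stats::setNames(bit_of(code, seq_len(k)), ins)
    structure(list(name = if (any(clamped == 1L))
      paste(ins[clamped == 1L], collapse = "+") else "none",
      clamped = clamped), class = "environment_spec")
  })
}

#' Enumerate and classify attractors under a micro-environment
#'
#' Clamps the environment's extrinsic nodes and exhaustively enumerates the
#' remaining (intrinsic) sub-space; basin sizes sum to `2^(free nodes)`.
#'
#' @param net A `logic_network`.
#' @param env An `environment_spec` (see [make_environment()]).
#' @param rules Phenotype rules for labeling.
#' @return The `attractor_set` with a `labels` character vector attached
#'   (element `labels`), and the environment under `environment`.
#' @export
attractors_under_environment <- function(net, env, rules = phenotype_rules()) {
  if (!inherits(env, "environment_spec"))
    abort2("env must be an environment_spec (see make_environment)")
  attrs <- enumerate_attractors(net, clamp = env$clamped)
  attrs$labels <- classify_attractors(attrs, rules)
  attrs$environment <- env
  attrs
}

#' Simulate a knock-out or over-expression mutant
#'
#' The mutated node is clamped for the entire simulation (0 = knock-out,
#' 1 = over-expression) on top of an optional micro-environment, and the
#' clamped system's attractors are classified with the wild-type phenotype
#' rules. Clamping an input node this way is identical to fixing it through
#' the environment.
#'
#' @param net A `logic_network`.
#' @param node Mutated node name.
#' @param value 0 (knock-out) or 1 (over-expression).
#' @param env Optional `environment_spec` applied simultaneously.
#' @param rules Phenotype rules for labeling.
#' @return Labeled `attractor_set` (as in [attractors_under_environment()]).
#' @export
simulate_mutant <- function(net, node, value, env = NULL,
                            rules = phenotype_rules()) {
  if (!node %in% net$nodes) abort2("unknown node '", node, "'")
  clamp <- stats::setNames(as.integer(value), node)
  if (!is.null(env)) {
    if (node %in% names(env$clamped) && env$clamped[[node]] != value)
      abort2("conflicting clamps on node '", node, "'")
    clamp <- c(env$clamped[setdiff(names(env$clamped), node)], clamp)
  }
  attrs <- enumerate_attractors(net, clamp = clamp)
  attrs$labels <- classify_attractors(attrs, rules)
  attrs$mutant <- list(node = node, value = as.integer(value),
                       mode = if (value == 0) "knockout" else "overexpression")
  attrs$environment <- env
  attrs
}

#' Scan attractors and basins across micro-environments
#'
#' Runs [attractors_under_environment()] over every fully specified
#' extrinsic assignment (`2^k` environments) plus the named polarizing
#' presets, and tabulates basin size per phenotype class and environment.
#'
#' @param net A `logic_network`.
#' @param rules Phenotype rules.
#' @param include_presets Include the named presets as additional rows.
#' @return List with `table` (data frame: environment, scope, label,
#'   attractors, basin) and `runs` (the labeled attractor sets, named by
#'   environment).
#' @export
environment_scan <- function(net, rules = phenotype_rules(),
                             include_presets = TRUE) {
  envs <- all_environments(net)
  scopes <- rep("combination", length(envs))
  if (include_presets) {
    pres <- lapply(names(ENV_PRESETS), function(p) make_environment(net, p))
    envs <- c(envs, pres)
    scopes <- c(scopes, rep("preset", length(pres)))
  }
  runs <- vector("list", length(envs))
  rows <- vector("list", length(envs))
  for (i in seq_along(envs)) {
    a <- attractors_under_environment(net, envs[[i]], rules)
    runs[[i]] <- a
    basins <- vapply(a$attractors, function(x) x$basin_size, numeric(1))
    agg <- tapply(basins, a$labels, sum)
    cnt <- tapply(basins, a$labels, length)
    rows[[i]] <- data.frame(environment = envs[[i]]$name, scope = scopes[i],
                            label = names(agg),
                            attractors = as.integer(cnt),
                            basin = as.integer(agg),
                            row.names = NULL)
  }
  names(runs) <- vapply(seq_along(envs), function(i)
    paste0(scopes[i], ":", envs[[i]]$name), character(1))
  tab <- do.call(rbind, rows)
  if (include_presets) {
    # the "ALL" preset row: aggregate over every extrinsic combination
    comb <- tab[tab$scope == "combination", , drop = FALSE]
    agg_b <- tapply(comb$basin, comb$label, sum)
    agg_n <- tapply(comb$attractors, comb$label, sum)
    tab <- rbind(tab, data.frame(environment = "ALL", scope = "preset",
                                 label = names(agg_b),
                                 attractors = as.integer(agg_n),
                                 basin = as.integer(agg_b), row.names = NULL))
  }
  list(table = tab, runs = runs)
}
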