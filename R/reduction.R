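# Logical network reduction by variable substitution.
#
# A non-self-regulated node is eliminated by inlining its own update rule
# into every rule that references it; regulator sets are re-derived and
# truth tables recomputed exactly, so the regulatory logic (including
# indirect effects) is preserved. The method targets fixed points: every
# fixed point of the original network, projected onto the kept nodes, is a
# fixed point of the reduced network. Synchronous cycles are NOT guaranteed
# to be preserved.

is_self_regulated <- function(net, node) {
  r <- net$rules[[node]]
  j <- match(node, r$regulators)
  if (is.na(j)) return(FALSE)
  # genuine dependence, not just a listed-but-ineffective regulator
  k <- length(r$regulators)
  codes <- 0:(2L^k - 1L)
  b <- bit_of(codes, j)
  !identical(r$table[codes[b == 0L] + 1L], r$table[codes[b == 1L] + 1L])
}

#' Eliminate one node by rule substitution
#'
#' @param net A `logic_network`.
#' @param node Node to remove; must not (effectively) regulate itself and
#'   must not be an input.
#' @param max_regulators Refuse inlining if any rewritten rule would exceed
#'   this many regulators.
#' @return The reduced network (one node fewer).
#' @export
substitute_node <- function(net, node, max_regulators = 16L) {
  if (!node %in% net$nodes) abort2("unknown node '", node, "'")
  if (node %in% net$inputs)
    abort2("node '", node, "' is an input; inputs are not removed")
  if (is_self_regulated(net, node))
    abort2("node '", node, "' is self-regulated and cannot be substituted")
  sub <- net$rules[[node]]
  new_rules <- list()
  for (nd in setdiff(net$nodes, node)) {
    r <- net$rules[[nd]]
    if (!node %in% r$regulators) { new_rules[[nd]] <- r; next }
    regs <- unique(c(setdiff(r$regulators, node), sub$regulators))
    if (length(regs) > max_regulators)
      abort2("inlining '", node, "' into '", nd, "' would need ",
             length(regs), " regulators (cap ", max_regulators, ")")
    k <- length(regs)
    codes <- 0:(2L^k - 1L)
    val <- function(name) bit_of(codes, match(name, regs))
    # value of the removed node under each assignment
    vsub <- if (!length(sub$regulators)) rep(sub$table[1], length(codes)) else {
      idx <- rep(1L, length(codes))
      for (j in seq_along(sub$regulators))
        idx <- idx + val(sub$regulators[j]) * 2L^(j - 1L)
      sub$table[idx]
    }
    idx <- rep(1L, length(codes))
    for (j in seq_along(r$regulators)) {
      v <- if (r$regulators[j] == node) vsub else val(r$regulators[j])
      idx <- idx + v * 2L^(j - 1L)
    }
    tab <- r$table[idx]
    # drop regulators the new table does not actually depend on
    dep <- vapply(seq_len(k), function(j) {
      b <- bit_of(codes, j)
      !identical(tab[codes[b == 0L] + 1L], tab[codes[b == 1L] + 1L])
    }, logical(1))
    if (!all(dep)) {
      keepr <- regs[dep]
      kk <- length(keepr)
      sub_codes <- 0:(2L^kk - 1L)
      full <- rep(1L, length(sub_codes))
      for (j in seq_len(kk))
        full <- full + bit_of(sub_codes, j) * 2L^(match(keepr[j], regs) - 1L)
      tab <- tab[full]
      regs <- keepr
    }
    new_rules[[nd]] <- logic_rule(nd, regs, tab)
  }
  cats <- net$categories
  if (!is.null(cats)) cats <- cats[names(cats) != node]
  logic_network(new_rules, inputs = setdiff(net$inputs, node),
                categories = cats, metadata = net$metadata)
}

#' Reduce a network along an elimination order, with verification
#'
#' Applies [substitute_node()] for each node of `remove_order` in turn.
#' When the original state space is small enough to enumerate, the report
#' compares fixed points (projected onto the kept nodes) before and after;
#' otherwise a supplied list of required configurations over kept nodes is
#' checked against the reduced network's fixed points.
#'
#' @param net A `logic_network`.
#' @param remove_order Character vector of nodes to eliminate, in order.
#' @param required Optional matrix/data frame of required configurations
#'   (columns = kept nodes) checked in the report.
#' @param enumerate_cap Enumerate exactly when `2^n` is below this.
#' @param max_regulators Passed to [substitute_node()].
#' @return List: `network` (reduced), `report` (data frame of checked
#'   configurations with a `preserved` flag), `ok` (all preserved?),
#'   `note` on cycle non-preservation.
#' @export
reduce_network <- function(net, remove_order, required = NULL,
                           enumerate_cap = 2L^20, max_regulators = 16L) {
  red <- net
  for (nd in remove_order) red <- substitute_node(red, nd, max_regulators)
  kept <- red$nodes
  report <- NULL; ok <- NA
  fp_mat <- function(n) {
    at <- enumerate_attractors(n, cap = enumerate_cap)
    fps <- Filter(function(a) a$period == 1L, at$attractors)
    do.call(rbind, lapply(fps, function(a) a$states))
  }
  if (2^n_nodes(net) <= enumerate_cap) {
    before <- unique(fp_mat(net)[, kept, drop = FALSE])
    after <- fp_mat(red)[, kept, drop = FALSE]
    key <- function(m) apply(m, 1L, paste, collapse = "")
    preserved <- key(before) %in% key(after)
    report <- data.frame(configuration = key(before), preserved = preserved)
    ok <- all(preserved)
  } else if (!is.null(required)) {
    req <- as.matrix(required)[, kept, drop = FALSE]
    after <- fp_mat(red)[, kept, drop = FALSE]
    key <- function(m) apply(m, 1L, paste, collapse = "")
    preserved <- key(req) %in% key(after)
    report <- data.frame(configuration = key(req), preserved = preserved)
    ok <- all(preserved)
  }
  list(network = red, report = report, ok = ok,
       note = paste("fixed-point projection check only;",
                    "synchronous cycles are not guaranteed to be preserved"))
}
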