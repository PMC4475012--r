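# Functional robustness: single truth-table bit flips.
#
# One entry of one rule's truth table is flipped and the full dynamics is
# re-derived. For every initial state (the complete state space with inputs
# free) the final attractor of the altered network is compared, by canonical
# state set, with that of the unaltered network. The changed-attractor
# fraction is the proportion of (flip, initial state) pairs whose final
# attractor differs; the novel-attractor fraction counts pairs whose final
# attractor does not exist in the original network at all.

#' Flip one truth-table entry of a rule
#'
#' @param net A `logic_network`.
#' @param target Node whose rule is altered.
#' @param row Truth-table row index (1-based, `1..2^k`).
#' @return The altered network (the original is untouched). Flipping the
#'   same entry twice restores the original network.
#' @export
apply_flip <- function(net, target, row) {
  if (!target %in% net$nodes) abort2("unknown node '", target, "'")
  r <- net$rules[[target]]
  if (row < 1L || row > length(r$table))
    abort2("row ", row, " out of range for rule of '", target, "' (",
           length(r$table), " entries)")
  r$table[row] <- 1L - r$table[row]
  net$rules[[target]] <- r
  net
}

flip_universe <- function(net, include_inputs = FALSE) {
  nodes <- if (include_inputs) net$nodes else setdiff(net$nodes, net$inputs)
  do.call(rbind, lapply(nodes, function(nd) {
    data.frame(target = nd,
               row = seq_len(length(net$rules[[nd]]$table)))
  }))
}

attractor_keys <- function(cycles) {
  vapply(cycles, function(cod) paste(sort(cod), collapse = ","), character(1))
}

node_index_vector <- function(net, nd, codes, pos) {
  r <- net$rules[[nd]]
  k <- length(r$regulators)
  if (k == 0L) return(rep(1L, length(codes)))
  idx <- rep(1L, length(codes))
  for (j in seq_len(k))
    idx <- idx + bit_of(codes, pos[[r$regulators[j]]]) * 2L^(j - 1L)
  idx
}

#' Functional robustness to single rule-entry flips
#'
#' Evaluates single bit flips of the update rules (input identity rules are
#' structural and excluded by default) over the complete state space with
#' inputs free. Fractions are micro-averaged over all (flip, initial state)
#' pairs. Exhaustive mode covers every flip; sampled mode draws a stratified
#' sample of flips (evenly across nodes) with a recorded seed.
#'
#' @param net A `logic_network`.
#' @param mode `"auto"` (exhaustive if within `cap_pairs`, else sampled),
#'   `"exhaustive"` or `"sampled"`.
#' @param n_flips Number of flips to sample in sampled mode.
#' @param seed RNG seed for sampled mode (recorded in the result).
#' @param cap_pairs Refuse/avoid exhaustive evaluation beyond this many
#'   (flip, state) pairs.
#' @param include_inputs Also flip entries of input identity rules.
#' @return List of class `robustness_result`: `flips_evaluated`,
#'   `n_pairs`, `changed_attractor_fraction`, `novel_attractor_fraction`
#'   (both in `[0,1]`), `mode`, `seed`, `per_flip` detail data frame.
#' @export
functional_robustness <- function(net, mode = c("auto", "exhaustive", "sampled"),
                                  n_flips = 100L, seed = 1L,
                                  cap_pairs = 1e8, include_inputs = FALSE) {
  mode <- match.arg(mode)
  sm <- successor_map(net)
  N <- sm$N
  codes <- 0:(N - 1L)
  pos <- stats::setNames(seq_along(sm$free), sm$free)
  dec0 <- decompose_successor(sm$succ)
  keys0 <- attractor_keys(dec0$cycles)
  key_state0 <- keys0[dec0$label]

  universe <- flip_universe(net, include_inputs)
  total_pairs <- nrow(universe) * as.numeric(N)
  if (mode == "auto")
    mode <- if (total_pairs <= cap_pairs) "exhaustive" else "sampled"
  if (mode == "exhaustive" && total_pairs > cap_pairs)
    abort2("exhaustive robustness needs ", format(total_pairs, big.mark = ","),
           " (flip, state) pairs, above cap_pairs; use sampled mode")
  flips <- if (mode == "exhaustive") universe else {
    with_seed(seed, {
      # stratified: cycle over nodes, sampling rows without replacement per node
      by_node <- split(seq_len(nrow(universe)), universe$target)
      picks <- integer(0)
      avail <- lapply(by_node, function(ix) sample(ix))
      i <- 1L
      while (length(picks) < min(n_flips, nrow(universe))) {
        for (nd in names(avail)) {
          if (length(avail[[nd]]) >= i) picks <- c(picks, avail[[nd]][i])
          if (length(picks) >= min(n_flips, nrow(universe))) break
        }
        i <- i + 1L
      }
      universe[sort(picks), , drop = FALSE]
    })
  }

  changed <- numeric(nrow(flips)); novel <- numeric(nrow(flips))
  cur_nd <- ""
  idx <- NULL; bitw <- NULL; tab <- NULL
  for (i in seq_len(nrow(flips))) {
    nd <- flips$target[i]; row <- flips$row[i]
    if (nd != cur_nd) {
      idx <- node_index_vector(net, nd, codes, pos)
      bitw <- 2L^(pos[[nd]] - 1L)
      tab <- net$rules[[nd]]$table
      cur_nd <- nd
    }
    delta <- if (tab[row] == 1L) -bitw else bitw
    succ_f <- sm$succ
    hit <- idx == row
    succ_f[hit] <- succ_f[hit] + delta
    dec <- decompose_successor(succ_f)
    keys_f <- attractor_keys(dec$cycles)
    key_state <- keys_f[dec$label]
    changed[i] <- mean(key_state != key_state0)
    novel[i] <- mean(!(keys_f %in% keys0)[dec$label])
  }
  structure(list(
    flips_evaluated = nrow(flips),
    n_pairs = nrow(flips) * as.numeric(N),
    changed_attractor_fraction = mean(changed),
    novel_attractor_fraction = mean(novel),
    mode = mode,
    seed = if (mode == "sampled") as.integer(seed) else NA_integer_,
    per_flip = data.frame(target = flips$target, row = flips$row,
                          changed_fraction = changed, novel_fraction = novel)),
    class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf(
    "robustness_result (%s): %d flips, %.0f pairs\n  changed %.4f%% | novel %.4f%%\n",
    x$mode, x$flips_evaluated, x$n_pairs,
    100 * x$changed_attractor_fraction, 100 * x$novel_attractor_fraction))
  invisible(x)
}
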