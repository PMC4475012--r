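# Seeded generators of synthetic logical networks.
#
# These provide networks with the same structural contract as the bundled
# CD4 models (named nodes, truth-table rules, designated identity-rule
# inputs) so that every pipeline stage can be exercised with known ground
# truth, independently of the biological model.

#' Generate a random Boolean network
#'
#' Each non-input node receives `k` distinct regulators drawn uniformly and
#' a random truth table whose entries are 1 with probability `bias`.
#' Generation is a pure function of the arguments: the same spec yields an
#' identical network.
#'
#' @param n_nodes Total number of nodes.
#' @param k Regulators per node (scalar, or length-2 range sampled per node);
#'   must be `< n_nodes`.
#' @param bias Probability that a truth-table entry is 1.
#' @param n_inputs Number of identity-rule input nodes.
#' @param seed Integer seed.
#' @return A validated `logic_network` (nodes `N1..Nn`, inputs first).
#' @export
random_network <- function(n_nodes, k = 2L, bias = 0.5, n_inputs = 0L,
                           seed = 1L) {
  if (max(k) >= n_nodes) abort2("k must be < n_nodes")
  if (bias < 0 || bias > 1) abort2("bias must lie in [0,1]")
  if (n_inputs >= n_nodes) abort2("n_inputs must be < n_nodes")
  nodes <- paste0("N", seq_len(n_nodes))
  inputs <- nodes[seq_len(n_inputs)]
  with_seed(seed, {
    rules <- lapply(nodes, function(nd) {
      if (nd %in% inputs) return(identity_rule(nd))
      ki <- if (length(k) > 1L) sample(seq(k[1], k[2]), 1L) else k
      regs <- sample(nodes, ki)
      tab <- as.integer(stats::runif(2^ki) < bias)
      logic_rule(nd, regs, tab)
    })
    logic_network(rules, inputs = inputs,
                  metadata = list(generator = "random_network", seed = seed,
                                  bias = bias, k = k))
  })
}

#' Generate a random network with a planted fixed point
#'
#' Starts from [random_network()] and adjusts, for every node, the single
#' truth-table entry addressed by the pattern's regulator values so that the
#' pattern maps to itself. The plant is verified by direct evaluation.
#'
#' @param n_nodes Number of nodes.
#' @param pattern 0/1 vector of length `n_nodes` (the planted fixed point).
#' @param seed Integer seed.
#' @param k,bias,n_inputs Passed to [random_network()]; input nodes keep
#'   their pattern value automatically (identity rule).
#' @return A `logic_network` for which `pattern` is a fixed point.
#' @export
planted_fixed_point_network <- function(n_nodes, pattern, seed = 1L,
                                        k = 2L, bias = 0.5, n_inputs = 0L) {
  if (length(pattern) != n_nodes) abort2("pattern length must equal n_nodes")
  net <- random_network(n_nodes, k = k, bias = bias, n_inputs = n_inputs,
                        seed = seed)
  state <- stats::setNames(as.integer(pattern), net$nodes)
  for (nd in setdiff(net$nodes, net$inputs)) {
    r <- net$rules[[nd]]
    idx <- if (!length(r$regulators)) 1L else
      1L + sum(state[r$regulators] * 2L^(seq_along(r$regulators) - 1L))
    r$table[idx] <- state[[nd]]
    net$rules[[nd]] <- r
  }
  stopifnot(identical(synchronous_step(net, state), state))
  net$metadata$planted <- unname(state)
  net
}

#' Small hand-enumerable fixture networks
#'
#' Named toy models with known attractor structure:
#' * `toggle`: mutual inhibition `A = !B`, `B = !A` - fixed points (1,0) and
#'   (0,1) plus the synchronous 2-cycle (0,0) <-> (1,1);
#' * `relay_toggle`: `A = !B`, `B = A` - a single period-4 cycle;
#' * `chain`: `A = A`, `B = A`, `C = B` - attractors follow A;
#' * `self_activator`: `A = A` - fixed points 0 and 1;
#' * `ffl`: coherent feed-forward loop `A = A`, `B = A`, `C = A & B`.
#'
#' @return Named list of `logic_network` objects.
#' @export
toy_model_suite <- function() {
  list(
    toggle = logic_network(list(rule_from_expression("A", "!B"),
                                rule_from_expression("B", "!A"))),
    relay_toggle = logic_network(list(rule_from_expression("A", "!B"),
                                      rule_from_expression("B", "A"))),
    chain = logic_network(list(rule_from_expression("A", "A"),
                               rule_from_expression("B", "A"),
                               rule_from_expression("C", "B")),
                          inputs = "A"),
    self_activator = logic_network(list(rule_from_expression("A", "A")),
                                   inputs = character(0)),
    ffl = logic_network(list(rule_from_expression("A", "A"),
                             rule_from_expression("B", "A"),
                             rule_from_expression("C", "A & B")),
                        inputs = "A")
  )
}
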