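#' Evaluate one update rule on a network state
#'
#' @param rule A `logic_rule`.
#' @param state Named integer vector of node values; must assign every
#'   regulator of the rule.
#' @return The rule's output bit (0 or 1).
#' @export
evaluate_rule <- function(rule, state) {
  if (!length(rule$regulators)) return(rule$table[1])
  vals <- state[rule$regulators]
  if (anyNA(vals))
    abort2("state does not assign regulator(s) of node '", rule$target, "': ",
           paste(rule$regulators[is.na(vals)], collapse = ", "))
  idx <- 1L + sum(as.integer(vals) * 2L^(seq_along(vals) - 1L))
  rule$table[idx]
}

#' Apply one synchronous update step
#'
#' Every node is updated simultaneously from the same source state. Input
#' nodes carry the identity rule, so they never change along a trajectory.
#'
#' @param net A `logic_network`.
#' @param state Named integer vector, total over `net$nodes`.
#' @return The successor state (named integer vector in declaration order).
#' @export
synchronous_step <- function(net, state) {
  if (!all(net$nodes %in% names(state)))
    abort2("state must assign every node of the network")
  src <- state[net$nodes]
  out <- vapply(net$rules, evaluate_rule, integer(1), state = src)
  stats::setNames(as.integer(out), net$nodes)
}

## ---- integer-coded state spaces ------------------------------------------
## Free nodes are bit-packed with the first free node in the least
## significant bit. Clamped nodes are held at their clamp value.

check_clamp <- function(net, clamp) {
  if (is.null(clamp) || !length(clamp)) return(integer(0))
  clamp <- stats::setNames(as.integer(clamp), names(clamp))
  bad <- setdiff(names(clamp), net$nodes)
  if (length(bad)) abort2("clamp names unknown node(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(names(clamp))) {
    dup <- unique(names(clamp)[duplicated(names(clamp))])
    vals <- split(clamp, names(clamp))
    for (d in dup) if (length(unique(vals[[d]])) > 1L)
      abort2("conflicting clamps on node '", d, "'")
    clamp <- clamp[!duplicated(names(clamp))]
  }
  if (!all(clamp %in% c(0L, 1L))) abort2("clamp values must be 0 or 1")
  clamp
}

# Build the successor map over the free-node state space.
# Returns 0-based integer vector succ of length 2^(number of free nodes).
successor_map <- function(net, clamp = NULL, cap = 2L^22) {
  clamp <- check_clamp(net, clamp)
  free <- setdiff(net$nodes, names(clamp))
  nf <- length(free)
  if (2^nf > cap)
    abort2("state space 2^", nf, " exceeds the exhaustive-enumeration cap (",
           cap, " states); use sampling or clamp more nodes")
  N <- 2L^nf
  codes <- 0:(N - 1L)
  pos <- stats::setNames(seq_along(free), free)
  succ <- integer(N)
  for (nd in free) {
    r <- net$rules[[nd]]
    k <- length(r$regulators)
    if (k == 0L) {
      nxt <- rep(r$table[1], N)
    } else {
      idx <- rep(1L, N)
      for (j in seq_len(k)) {
        reg <- r$regulators[j]
        v <- if (reg %in% names(clamp)) rep(clamp[[reg]], N)
             else bit_of(codes, pos[[reg]])
        idx <- idx + v * 2L^(j - 1L)
      }
      nxt <- r$table[idx]
    }
    succ <- succ + nxt * 2L^(pos[[nd]] - 1L)
  }
  list(succ = succ, free = free, clamp = clamp, N = N)
}

# Full attractor/basin decomposition of the functional graph of `succ`.
# Returns: cycles (list of 0-based code vectors, in trajectory order),
# label (attractor index per state, 1-based over states 1..N), basin sizes.
decompose_successor <- function(succ) {
  N <- length(succ)
  s1 <- succ + 1L
  G <- s1
  reps <- max(1L, ceiling(log2(N)))
  for (i in seq_len(reps)) G <- G[G]
  cyc_states <- unique(G)           # exactly the states on cycles (1-based)
  aid <- integer(N)
  cycles <- list()
  for (c0 in cyc_states) {
    if (aid[c0] != 0L) next
    id <- length(cycles) + 1L
    path <- c0
    nxt <- s1[c0]
    while (nxt != c0) { path <- c(path, nxt); nxt <- s1[nxt] }
    aid[path] <- id
    cycles[[id]] <- path - 1L
  }
  label <- aid[G]
  list(cycles = cycles, label = label,
       basin = tabulate(label, nbins = length(cycles)))
}

decode_states <- function(codes, free, clamp, nodes) {
  m <- matrix(0L, nrow = length(codes), ncol = length(nodes),
              dimnames = list(NULL, nodes))
  for (j in seq_along(free)) m[, free[j]] <- bit_of(codes, j)
  for (nd in names(clamp)) m[, nd] <- clamp[[nd]]
  m
}

encode_state <- function(state, free) {
  v <- as.integer(state[free])
  sum(v * 2L^(seq_along(free) - 1L))
}

# lexicographic sort key over declaration order (first node most significant)
state_lex_key <- function(mat) apply(mat, 1L, paste, collapse = "")

canonical_rotation <- function(codes, free, clamp, nodes) {
  if (length(codes) == 1L) return(1L)
  keys <- state_lex_key(decode_states(codes, free, clamp, nodes))
  order(keys)[1]
}

#' Enumerate all attractors and basins of a network
#'
#' Exhaustively simulates the synchronous dynamics over the state space of
#' the unclamped ("free") nodes; clamped nodes are held constant. Every
#' state is assigned to exactly one attractor, so basin sizes sum to the
#' number of enumerated states. Cyclic attractors are reported alongside
#' fixed points; each attractor is rotated so that its lexicographically
#' smallest state (in node declaration order) comes first.
#'
#' @param net A `logic_network`.
#' @param clamp Optional named 0/1 vector of nodes to hold constant (a
#'   micro-environment when restricted to inputs, a mutant otherwise).
#' @param cap Refuse exhaustive enumeration beyond this many states.
#' @return An `attractor_set`: list with `attractors` (each a list with
#'   `states` matrix over all nodes, `period`, `basin_size`), plus the free
#'   nodes and clamp used.
#' @export
enumerate_attractors <- function(net, clamp = NULL, cap = 2L^22) {
  sm <- successor_map(net, clamp, cap)
  dec <- decompose_successor(sm$succ)
  ord <- seq_along(dec$cycles)
  att <- lapply(ord, function(i) {
    codes <- dec$cycles[[i]]
    rot <- canonical_rotation(codes, sm$free, sm$clamp, net$nodes)
    codes <- c(codes[rot:length(codes)], codes[seq_len(rot - 1L)])
    list(states = decode_states(codes, sm$free, sm$clamp, net$nodes),
         codes = codes,
         period = length(codes),
         basin_size = dec$basin[i])
  })
  keys <- vapply(att, function(a) state_lex_key(a$states[1, , drop = FALSE]),
                 character(1))
  att <- att[order(keys)]
  structure(list(attractors = att, free = sm$free, clamp = sm$clamp,
                 nodes = net$nodes, n_states = sm$N),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  cat("attractor_set: ", length(x$attractors), " attractor(s) over ",
      x$n_states, " states\n", sep = "")
  for (i in seq_along(x$attractors)) {
    a <- x$attractors[[i]]
    on <- colnames(a$states)[colSums(a$states) == a$period]
    cat(sprintf("  [%d] period %d, basin %d, active: %s\n", i, a$period,
                a$basin_size,
                if (length(on)) paste(on, collapse = "+") else "none"))
  }
  invisible(x)
}

#' Flatten an attractor set to a data frame (one row per attractor state)
#'
#' @param x An `attractor_set`.
#' @param row.names,optional Ignored (S3 signature).
#' @param labels Optional character vector of phenotype labels, one per
#'   attractor, appended as a `phenotype` column.
#' @param ... Unused.
#' @return A data frame with node columns plus `attractor`, `state`,
#'   `period`, `basin_size` (and `phenotype` if given).
#' @export
as.data.frame.attractor_set <- function(x, row.names = NULL, optional = FALSE,
                                        labels = NULL, ...) {
  rows <- lapply(seq_along(x$attractors), function(i) {
    a <- x$attractors[[i]]
    d <- as.data.frame(a$states)
    d$attractor <- i
    d$state <- seq_len(a$period)
    d$period <- a$period
    d$basin_size <- a$basin_size
    if (!is.null(labels)) d$phenotype <- labels[i]
    d
  })
  do.call(rbind, rows)
}

#' Follow a single trajectory to its attractor
#'
#' Iterates the synchronous map from `start` until a previously visited
#' state recurs, then reports the attractor (in canonical rotation) and the
#' number of steps taken before entering it.
#'
#' @param net A `logic_network`.
#' @param start Named 0/1 vector over all nodes.
#' @param clamp Optional clamp applied throughout (start must agree with it).
#' @param max_steps Safety bound; defaults to `2^n_nodes(net) + 1`, which
#'   guarantees termination for deterministic synchronous dynamics.
#' @return List with `attractor` (list: `states`, `period`), `transient`
#'   (steps before entering the attractor).
#' @export
find_attractor <- function(net, start, clamp = NULL,
                           max_steps = 2^n_nodes(net) + 1) {
  clamp <- check_clamp(net, clamp)
  state <- stats::setNames(as.integer(start[net$nodes]), net$nodes)
  if (anyNA(state)) abort2("start state must assign every node")
  state[names(clamp)] <- clamp
  seen <- new.env(hash = TRUE, parent = emptyenv())
  traj <- list()
  key <- function(s) paste(s, collapse = "")
  i <- 0L
  repeat {
    k <- key(state)
    hit <- get0(k, envir = seen)
    if (!is.null(hit)) {
      cyc <- traj[hit:length(traj)]
      mat <- do.call(rbind, cyc)
      colnames(mat) <- net$nodes
      rot <- order(state_lex_key(mat))[1]
      idx <- c(rot:nrow(mat), seq_len(rot - 1L))
      return(list(attractor = list(states = mat[idx, , drop = FALSE],
                                   period = nrow(mat)),
                  transient = hit - 1L))
    }
    assign(k, i + 1L, envir = seen)
    traj[[i + 1L]] <- state
    state <- synchronous_step(net, state)
    state[names(clamp)] <- clamp
    i <- i + 1L
    if (i > max_steps)
      abort2("max_steps exhausted without cycle detection (engine bug?)")
  }
}
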