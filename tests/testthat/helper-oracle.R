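# Independent brute-force oracle for attractor enumeration: follows every
# state's trajectory with plain per-node rule evaluation (no shared code
# with the vectorized engine's functional-graph decomposition).

all_states_of <- function(net, clamp = NULL) {
  free <- setdiff(net$nodes, names(clamp))
  grid <- expand.grid(rep(list(0:1), length(free)), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- free
  grid
}

state_key <- function(state, nodes) paste(state[nodes], collapse = "")

brute_force_attractors <- function(net, clamp = NULL) {
  free <- setdiff(net$nodes, names(clamp))
  grid <- all_states_of(net, clamp)
  basins <- list()
  for (i in seq_len(nrow(grid))) {
    st <- stats::setNames(integer(length(net$nodes)), net$nodes)
    st[free] <- as.integer(grid[i, free])
    for (nd in names(clamp)) st[nd] <- clamp[[nd]]
    seen <- character(0)
    repeat {
      k <- state_key(st, net$nodes)
      hit <- match(k, seen)
      if (!is.na(hit)) {
        cyc <- sort(seen[hit:length(seen)])
        akey <- paste(cyc, collapse = "|")
        basins[[akey]] <- (basins[[akey]] %||% 0L) + 1L
        break
      }
      seen <- c(seen, k)
      st <- synchronous_step(net, st)
      for (nd in names(clamp)) st[nd] <- clamp[[nd]]
    }
  }
  basins
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical attractor keys for an engine attractor_set, in the oracle's format
engine_attractor_keys <- function(attrs) {
  vapply(attrs$attractors, function(a) {
    keys <- apply(a$states, 1L, paste, collapse = "")
    paste(sort(keys), collapse = "|")
  }, character(1))
}
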