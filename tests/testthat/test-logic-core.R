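test_that("rule evaluation handles identity, constant and missing regulators", {
  id <- identity_rule("A")
  expect_equal(evaluate_rule(id, c(A = 1L)), 1L)
  expect_equal(evaluate_rule(id, c(A = 0L)), 0L)
  const0 <- logic_rule("B", character(0), 0L)
  expect_equal(evaluate_rule(const0, c(A = 1L, B = 1L)), 0L)
  r <- rule_from_expression("C", "A & !B")
  expect_error(evaluate_rule(r, c(A = 1L)), "regulator")
  expect_equal(evaluate_rule(r, c(A = 1L, B = 0L)), 1L)
})

test_that("expression round trip preserves truth tables", {
  set.seed(7)
  for (i in 1:20) {
    k <- sample(1:4, 1)
    regs <- paste0("X", seq_len(k))
    tab <- sample(0:1, 2^k, replace = TRUE)
    r <- logic_rule("T", regs, tab)
    r2 <- rule_from_expression("T", expression_from_rule(r))
    expect_true(rules_equal <- cd4logic::networks_equivalent(
      logic_network(c(list(r), lapply(regs, identity_rule)), inputs = regs),
      logic_network(c(list(r2), lapply(regs, identity_rule)), inputs = regs)))
  }
})

test_that("synchronous step equals independent per-node rule evaluation", {
  set.seed(11)
  for (i in 1:10) {
    net <- random_network(3, k = 2, seed = i)
    for (code in 0:7) {
      st <- stats::setNames(c(code %% 2, code %/% 2 %% 2, code %/% 4), net$nodes)
      manual <- vapply(net$nodes, function(nd)
        evaluate_rule(net$rules[[nd]], st), integer(1))
      expect_equal(unname(synchronous_step(net, st)), unname(manual))
    }
  }
})

test_that("a fixed point maps to itself and has transient 0", {
  nets <- toy_model_suite()
  res <- find_attractor(nets$toggle, c(A = 1L, B = 0L))
  expect_equal(res$attractor$period, 1L)
  expect_equal(res$transient, 0L)
  expect_equal(synchronous_step(nets$toggle, c(A = 1L, B = 0L)),
               c(A = 1L, B = 0L))
})

test_that("the relay toggle (A = !B, B = A) cycles with period 4", {
  # hand enumeration: (1,0) -> (1,1) -> (0,1) -> (0,0) -> (1,0)
  net <- toy_model_suite()$relay_toggle
  res <- find_attractor(net, c(A = 1L, B = 0L))
  expect_equal(res$attractor$period, 4L)
  expect_equal(res$transient, 0L)
  traj <- list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(0L, 0L))
  st <- c(A = 1L, B = 0L)
  for (i in 2:4) {
    st <- synchronous_step(net, st)
    expect_equal(unname(st), traj[[i]])
  }
  expect_equal(unname(synchronous_step(net, st)), traj[[1]])
  # canonical rotation starts at the lexicographically smallest state (0,0)
  at <- enumerate_attractors(net)
  expect_equal(length(at$attractors), 1L)
  expect_equal(unname(at$attractors[[1]]$states[1, ]), c(0L, 0L))
})

test_that("constant network has a single attractor with full basin", {
  rules <- lapply(c("A", "B", "C"), function(nd) logic_rule(nd, character(0), 0L))
  net <- logic_network(rules)
  at <- enumerate_attractors(net)
  expect_equal(length(at$attractors), 1L)
  expect_equal(at$attractors[[1]]$basin_size, 8L)
})

test_that("enumeration agrees with the brute-force trajectory oracle", {
  for (seed in 1:3) {
    net <- random_network(10, k = 2, n_inputs = 2, seed = seed)
    at <- enumerate_attractors(net)
    oracle <- brute_force_attractors(net)
    keys <- engine_attractor_keys(at)
    expect_setequal(keys, names(oracle))
    basins <- stats::setNames(
      vapply(at$attractors, function(a) a$basin_size, numeric(1)), keys)
    for (k in names(oracle))
      expect_equal(unname(basins[k]), unname(oracle[[k]]))
  }
  # also under a clamp
  net <- random_network(8, k = 2, n_inputs = 2, seed = 5)
  clamp <- stats::setNames(c(1L, 0L), net$inputs)
  at <- enumerate_attractors(net, clamp = clamp)
  oracle <- brute_force_attractors(net, clamp = clamp)
  expect_setequal(engine_attractor_keys(at), names(oracle))
})

test_that("basin sizes partition the enumerated state space", {
  for (seed in 1:5) {
    net <- random_network(9, k = c(1, 3), n_inputs = 3, seed = seed)
    at <- enumerate_attractors(net)
    expect_equal(sum(vapply(at$attractors, function(a) a$basin_size,
                            numeric(1))), 2^9)
    clamp <- stats::setNames(rep(1L, 3), net$inputs)
    atc <- enumerate_attractors(net, clamp = clamp)
    expect_equal(sum(vapply(atc$attractors, function(a) a$basin_size,
                            numeric(1))), 2^6)
  }
})

test_that("input nodes never change along any trajectory", {
  net <- random_network(8, k = 2, n_inputs = 3, seed = 42)
  at <- enumerate_attractors(net)
  for (a in at$attractors) {
    for (inp in net$inputs)
      expect_true(all(a$states[, inp] == a$states[1, inp]))
  }
  st <- stats::setNames(c(1L, 0L, 1L, rep(0L, 5)), net$nodes)
  for (i in 1:10) {
    st2 <- synchronous_step(net, st)
    expect_equal(st2[net$inputs], st[net$inputs])
    st <- st2
  }
})

test_that("canonical form is idempotent and stepping is deterministic", {
  net <- random_network(7, k = 2, seed = 3)
  at <- enumerate_attractors(net)
  at2 <- enumerate_attractors(net)
  expect_identical(at, at2)
  for (a in at$attractors) {
    keys <- apply(a$states, 1, paste, collapse = "")
    expect_equal(keys[1], sort(keys)[1])  # smallest state first
  }
})

test_that("enumeration beyond the cap is refused with a clear message", {
  net <- random_network(12, k = 2, seed = 1)
  expect_error(enumerate_attractors(net, cap = 2^10), "cap")
})
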