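rules_equal_nets <- function(a, b, nodes) {
  all(vapply(nodes, function(nd)
    identical(a$rules[[nd]]$table, b$rules[[nd]]$table) &&
      identical(a$rules[[nd]]$regulators, b$rules[[nd]]$regulators),
    logical(1)))
}

chain_net <- function() {
  logic_network(list(identity_rule("A"),
                     rule_from_expression("B", "A"),
                     rule_from_expression("C", "B")),
                inputs = "A")
}

test_that("removing a pass-through node rewires its target", {
  red <- substitute_node(chain_net(), "B")
  expect_setequal(red$nodes, c("A", "C"))
  expect_equal(red$rules$C$regulators, "A")
  expect_equal(red$rules$C$table, c(0L, 1L))
})

test_that("sign propagates through an inverting intermediate", {
  net <- logic_network(list(identity_rule("A"),
                            rule_from_expression("B", "!A"),
                            rule_from_expression("C", "B")),
                       inputs = "A")
  red <- substitute_node(net, "B")
  expect_equal(evaluate_rule(red$rules$C, c(A = 0L)), 1L)
  expect_equal(evaluate_rule(red$rules$C, c(A = 1L)), 0L)
})

test_that("self-regulated nodes and inputs are refused", {
  net <- logic_network(list(rule_from_expression("A", "A | B"),
                            identity_rule("B"),
                            rule_from_expression("C", "A")),
                       inputs = "B")
  expect_error(substitute_node(net, "A"), "self-regulated")
  expect_error(substitute_node(net, "B"), "input")
  # a listed but ineffective self-reference is not self-regulation
  ineffective <- logic_network(list(
    logic_rule("A", c("A", "B"), c(0L, 0L, 1L, 1L)),  # depends on B only
    identity_rule("B"), rule_from_expression("C", "A")), inputs = "B")
  expect_silent(substitute_node(ineffective, "A"))
})

test_that("substitution commutes for nodes that do not regulate each other", {
  net <- logic_network(list(identity_rule("A"), identity_rule("D"),
                            rule_from_expression("B", "A"),
                            rule_from_expression("C", "!D"),
                            rule_from_expression("E", "B & C")),
                       inputs = c("A", "D"))
  bc <- substitute_node(substitute_node(net, "B"), "C")
  cb <- substitute_node(substitute_node(net, "C"), "B")
  expect_true(networks_equivalent(bc, cb))
})

test_that("fixed points project onto kept nodes through reduction", {
  for (seed in 1:5) {
    net <- random_network(8, k = 2, n_inputs = 2, seed = seed)
    removable <- Filter(function(nd) {
      !nd %in% net$inputs && !cd4logic:::is_self_regulated(net, nd)
    }, net$nodes)
    if (!length(removable)) next
    res <- reduce_network(net, removable[1])
    expect_true(isTRUE(res$ok))
  }
})

test_that("a planted fixed point survives reduction of removable nodes", {
  pattern <- c(1L, 0L, 1L, 1L, 0L, 1L, 0L, 0L)
  net <- planted_fixed_point_network(8, pattern, seed = 21, n_inputs = 2)
  removable <- Filter(function(nd) {
    !nd %in% net$inputs && !cd4logic:::is_self_regulated(net, nd)
  }, net$nodes)
  for (nd in removable) {
    res <- reduce_network(net, nd)
    kept <- res$network$nodes
    at <- enumerate_attractors(res$network)
    fps <- Filter(function(a) a$period == 1L, at$attractors)
    mats <- vapply(fps, function(a)
      paste(a$states[1, kept], collapse = ""), character(1))
    want <- paste(stats::setNames(pattern, net$nodes)[kept], collapse = "")
    expect_true(want %in% mats)
  }
})

test_that("an empty removal order returns the network unchanged", {
  net <- chain_net()
  res <- reduce_network(net, character(0))
  expect_true(networks_equivalent(net, res$network))
  expect_true(isTRUE(res$ok))
})

test_that("removing an output node leaves all other rules unchanged", {
  net <- chain_net()  # C has no targets
  red <- substitute_node(net, "C")
  expect_setequal(red$nodes, c("A", "B"))
  expect_true(rules_equal_nets(net, red, c("A", "B")))
})

test_that("inlining beyond the regulator cap is refused with a diagnostic", {
  net <- random_network(10, k = 3, seed = 6)
  victim <- setdiff(net$nodes, net$inputs)
  tried <- FALSE
  for (nd in victim) {
    if (cd4logic:::is_self_regulated(net, nd)) next
    err <- tryCatch({ substitute_node(net, nd, max_regulators = 3L); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(err) && grepl("cap", err)) { tried <- TRUE; break }
  }
  expect_true(tried)
})
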