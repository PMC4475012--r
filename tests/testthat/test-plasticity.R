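test_that("flipping the sustaining node of a bistable switch changes attractor", {
  net <- toy_model_suite()$self_activator
  at <- enumerate_attractors(net)
  on <- at$attractors[[which(vapply(at$attractors, function(a)
    a$states[1, "A"], integer(1)) == 1L)]]
  toy_rules <- data.frame(label = c("Aon", "Aoff"),
                          required_on = c("A", ""),
                          required_off = c("", "A"),
                          priority = 1:2)
  ev <- transient_perturb(net, on, "A", rules = toy_rules)
  expect_equal(ev$direction, "inhibition")
  expect_true(ev$is_transition)
  expect_equal(ev$outcome_label, "Aoff")
  # in the mutual-inhibition toggle the same flip lands in the synchronous
  # 2-cycle rather than the opposite fixed point
  tog <- toy_model_suite()$toggle
  att <- enumerate_attractors(tog)
  fps <- Filter(function(a) a$period == 1L, att$attractors)
  a10 <- fps[[which(vapply(fps, function(a) a$states[1, "A"], integer(1)) == 1L)]]
  tr <- data.frame(label = c("Aon", "Bon"), required_on = c("A", "B"),
                   required_off = c("B", "A"), priority = 1:2)
  ev2 <- transient_perturb(tog, a10, "A", rules = tr)
  expect_true(ev2$is_transition)
  expect_equal(ev2$outcome_attractor$period, 2L)
})

test_that("perturbing a node towards its current value is refused", {
  net <- toy_model_suite()$toggle
  at <- enumerate_attractors(net)
  a <- Filter(function(x) x$period == 1L, at$attractors)[[1]]
  cur <- a$states[1, "A"]
  wrong <- if (cur == 1L) "activation" else "inhibition"
  expect_error(transient_perturb(net, a, "A", direction = wrong),
               "not a perturbation")
})

test_that("perturbation accounting identities hold on the full scan", {
  scan <- tsrn_scan()
  tsrn <- tsrn_model()
  # one event per (environment, attractor, node)
  n_attr <- sum(vapply(all_environments(tsrn), function(env)
    length(enumerate_attractors(tsrn, clamp = env$clamped)$attractors),
    numeric(1)))
  expect_equal(nrow(scan$events), n_attr * n_nodes(tsrn))
  fm <- build_fate_map(scan)
  expect_equal(sum(fm$edges$count) + sum(fm$self_loops$count),
               nrow(scan$events))
  st <- transition_statistics(scan)
  expect_equal(st$n_transitions + sum(!scan$events$is_transition),
               st$n_perturbations)
  # per-node and per-category tallies reconcile with the overall tally
  per_node_n <- tapply(scan$events$is_transition, scan$events$node, sum)
  expect_equal(sum(per_node_n), st$n_transitions)
  per_cat_n <- tapply(scan$events$is_transition, scan$events$category, sum)
  expect_equal(sum(per_cat_n), st$n_transitions)
  expect_true(all(scan$events$category[scan$events$node %in% tsrn$inputs]
                  == "extrinsic"))
})

test_that("the perturbation protocol is deterministic", {
  tsrn <- tsrn_model()
  env <- make_environment(tsrn, "Th1")
  s1 <- stability_score(tsrn, env)
  s2 <- stability_score(tsrn, env)
  expect_identical(s1, s2)
})

test_that("stability is the complement of the per-class transition fraction", {
  tsrn <- tsrn_model()
  env <- make_environment(tsrn, "iTreg")
  one_scan <- perturbation_scan(tsrn, environments = list(env))
  frac <- vapply(split(one_scan$events$is_transition,
                       one_scan$events$source_label), mean, numeric(1))
  sc <- stability_score(tsrn, env)
  expect_equal(sc[names(frac)], 1 - frac)
})

test_that("activation perturbations drive transitions more than inhibitions", {
  st <- transition_statistics(tsrn_scan())
  expect_gt(st$per_direction_fraction[["activation"]],
            st$per_direction_fraction[["inhibition"]])
})

test_that("fractions are proportions and directions partition the events", {
  st <- transition_statistics(tsrn_scan(), percent = FALSE)
  expect_true(all(st$per_node_fraction >= 0 & st$per_node_fraction <= 1))
  expect_true(st$overall_fraction >= 0 && st$overall_fraction <= 1)
  ev <- tsrn_scan()$events
  expect_equal(sum(ev$direction == "activation") +
                 sum(ev$direction == "inhibition"), nrow(ev))
  # direction is consistent with the perturbed node's value in the source state
  expect_error(transition_statistics(ev[0, ]), "empty")
})

test_that("the transition census counts ordered class pairs both ways", {
  cen <- count_class_transitions(tsrn_scan())
  expect_equal(cen$possible, length(cen$classes)^2)
  expect_true(cen$observed_cross <= cen$possible - length(cen$classes))
  expect_equal(nrow(cen$pairs), cen$observed_cross)
  # a single-attractor network: 1 possible pair, 0 observed cross
  net <- logic_network(list(logic_rule("A", character(0), 0L)))
  rules1 <- data.frame(label = "off", required_on = "", required_off = "A",
                       priority = 1)
  sc <- perturbation_scan(net, environments = list(
    structure(list(name = "none", clamped = integer(0)),
              class = "environment_spec")), rules = rules1)
  cen1 <- count_class_transitions(sc)
  expect_equal(cen1$possible, 1L)
  expect_equal(cen1$observed_cross, 0L)
})

test_that("fate maps export to GraphML and DOT with attributes", {
  fm <- build_fate_map(tsrn_scan())
  base <- tempfile()
  paths <- export_fate_map(fm, base)
  expect_true(all(file.exists(paths)))
  g <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_true("basin_size" %in% igraph::vertex_attr_names(g))
  expect_true("count" %in% igraph::edge_attr_names(g))
  # transitions toward Foxp3-independent regulatory states are present
  expect_true("TrFoxp3-" %in% fm$edges$to)
  expect_gt(length(unique(fm$edges$from[fm$edges$to == "TrFoxp3-"])), 1L)
})
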