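test_that("environments clamp only inputs and presets fix unlisted inputs at 0", {
  tsrn <- tsrn_model()
  env <- make_environment(tsrn, "iTreg")
  expect_equal(sort(names(env$clamped)), sort(tsrn$inputs))
  expect_equal(env$clamped[["TGFBe"]], 1L)
  expect_equal(env$clamped[["IL2e"]], 1L)
  expect_equal(env$clamped[["IFNGe"]], 0L)
  free <- make_environment(tsrn, "iTreg", free_unlisted = TRUE)
  expect_equal(sort(names(free$clamped)), c("IL2e", "TGFBe"))
  expect_error(make_environment(tsrn, clamped = c(FOXP3 = 1L)), "mutant")
})

test_that("basins partition the 4096-state intrinsic sub-space per environment", {
  tsrn <- tsrn_model()
  for (p in c("Th0", "Th1", "iTreg")) {
    a <- attractors_under_environment(tsrn, make_environment(tsrn, p))
    expect_equal(sum(vapply(a$attractors, function(x) x$basin_size,
                            numeric(1))), 4096)
  }
})

test_that("cytokine-free conditions lose Th17, iTreg and Th9 but keep the lineages", {
  tsrn <- tsrn_model()
  a0 <- attractors_under_environment(tsrn, make_environment(tsrn, "Th0"))
  expect_false(any(c("Th17", "iTreg", "Th9") %in% a0$labels))
  expect_true(all(c("Th0", "Th1", "Th2", "Tfh") %in% a0$labels))
})

test_that("polarizing presets recover their promoted cell types", {
  tsrn <- tsrn_model()
  expect_true("iTreg" %in%
    attractors_under_environment(tsrn, make_environment(tsrn, "iTreg"))$labels)
  expect_true("Th17" %in%
    attractors_under_environment(tsrn, make_environment(tsrn, "Th17"))$labels)
  expect_true("Th9" %in%
    attractors_under_environment(tsrn, make_environment(tsrn, "Th9"))$labels)
})

test_that("a regulatory TGF-B environment with IL-21 retains Th17", {
  tsrn <- tsrn_model()
  env <- make_environment(tsrn, clamped = c(IFNGe = 0L, IL2e = 0L, IL4e = 0L,
                                            IL21e = 1L, TGFBe = 1L, IL10e = 0L))
  expect_true("Th17" %in% attractors_under_environment(tsrn, env)$labels)
})

test_that("promoting a cell type never shrinks its basin relative to no cytokines", {
  tsrn <- tsrn_model()
  basin_of <- function(env, lab) {
    a <- attractors_under_environment(tsrn, env)
    sum(vapply(a$attractors, function(x) x$basin_size, numeric(1))[a$labels == lab])
  }
  e0 <- make_environment(tsrn, "Th0")
  for (p in c("Th1", "Th2", "Th17", "iTreg", "Tfh", "Th9"))
    expect_gte(basin_of(make_environment(tsrn, p), p), basin_of(e0, p))
})

test_that("clamping an input as environment or as mutant is equivalent", {
  tsrn <- tsrn_model()
  env <- make_environment(tsrn, clamped = c(IFNGe = 1L))
  via_env <- attractors_under_environment(tsrn, env)
  via_mut <- simulate_mutant(tsrn, "IFNGe", 1L)
  expect_equal(engine_attractor_keys(via_env), engine_attractor_keys(via_mut))
  expect_equal(via_env$labels, via_mut$labels)
})

test_that("conflicting clamps on one node are refused", {
  tsrn <- tsrn_model()
  env <- make_environment(tsrn, "Th1")  # IFNGe = 1
  expect_error(simulate_mutant(tsrn, "IFNGe", 0L, env), "conflicting clamps")
})

test_that("a knockout of a node already inactive leaves its attractor intact", {
  tsrn <- tsrn_model()
  env <- make_environment(tsrn, "Th0")
  wt <- attractors_under_environment(tsrn, env)
  th1 <- wt$attractors[[which(wt$labels == "Th1")[1]]]
  expect_equal(th1$states[1, "IL9"], c(IL9 = 0L))
  ko <- simulate_mutant(tsrn, "IL9", 0L, env)
  keys <- engine_attractor_keys(ko)
  th1key <- engine_attractor_keys(wt)[which(wt$labels == "Th1")[1]]
  expect_true(th1key %in% keys)
})

test_that("Foxp3 knockout still reaches Foxp3-independent regulatory states", {
  tsrn <- tsrn_model()
  found <- FALSE
  for (env in list(make_environment(tsrn, "iTreg"), make_environment(tsrn, "IL10"))) {
    m <- simulate_mutant(tsrn, "FOXP3", 0L, env)
    if ("TrFoxp3-" %in% m$labels) found <- TRUE
  }
  expect_true(found)
})

test_that("the environment scan covers all combinations plus the presets", {
  tsrn <- tsrn_model()
  sc <- environment_scan(tsrn)
  expect_length(sc$runs, 64 + 8)
  expect_setequal(unique(sc$table$scope), c("combination", "preset"))
  # 8 named polarizing presets plus the all-combinations aggregate = 9
  expect_length(unique(sc$table$environment[sc$table$scope == "preset"]), 9L)
  expect_true("ALL" %in% sc$table$environment)
})
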