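test_that("the oracle enumerates, counts and witnesses correctly", {
  ## single external, one copy node, tau = 1: exactly one of two sequences works
  net <- boolean_network(list(a = "u"), external = "u")
  p <- control_problem(net, c(a = 0), c(a = 1), tau = 1)
  res <- brute_force_solve(p)
  expect_true(res$decision)
  expect_equal(res$count_solutions, 1)
  expect_equal(unname(res$witness[1, ]), 1L)
  ## tau = 2 with a free first bit: two sequences work
  p2 <- control_problem(net, c(a = 0), c(a = 1), tau = 2)
  expect_equal(brute_force_solve(p2)$count_solutions, 2)
})

test_that("with no externals the oracle reduces to a single simulation", {
  net <- boolean_network(list(a = "b", b = "a"))
  traj <- bn_simulate(net, c(a = 1, b = 0), NULL, tau = 3)
  p_hit <- control_problem(net, c(a = 1, b = 0), traj[4, ], tau = 3)
  res <- brute_force_solve(p_hit)
  expect_true(res$decision)
  expect_equal(res$count_solutions, 1)
  p_miss <- control_problem(net, c(a = 1, b = 0), 1L - traj[4, ], tau = 3)
  expect_equal(brute_force_solve(p_miss)$count_solutions, 0)
})

test_that("every witness the oracle returns passes verification", {
  set.seed(5)
  for (i in 1:25) {
    inst <- random_instance(sample(2:6, 1), sample(1:2, 1), max_inputs = 3,
                            edge_density = stats::runif(1, 0.3, 0.9),
                            tau = sample(1:4, 1), seed = 4000 + i)
    res <- brute_force_solve(inst$problem)
    if (res$decision) expect_true(verify_control(inst$problem, res$witness))
  }
})

test_that("the sequence cap raises a resource error", {
  net <- boolean_network(list(a = "u1 | u2 | u3"),
                         external = c("u1", "u2", "u3"))
  p <- control_problem(net, c(a = 0), c(a = 1), tau = 10)
  expect_error(brute_force_solve(p, max_sequences = 2^20),
               class = "bn_resource_error")
})

test_that("identical seeds reproduce byte-identical instances", {
  a <- random_instance(6, 2, max_inputs = 3, edge_density = 0.6,
                       target_largest_scc = 2, tau = 3, seed = 77)
  b <- random_instance(6, 2, max_inputs = 3, edge_density = 0.6,
                       target_largest_scc = 2, tau = 3, seed = 77)
  fa <- tempfile(); fb <- tempfile()
  write_boolean_network(a$network, fa)
  write_boolean_network(b$network, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_identical(a$problem$initial, b$problem$initial)
  expect_identical(a$problem$desired, b$problem$desired)
  ## different seeds give different instances
  c_ <- random_instance(6, 2, max_inputs = 3, edge_density = 0.6,
                        target_largest_scc = 2, tau = 3, seed = 78)
  fc <- tempfile()
  write_boolean_network(c_$network, fc)
  expect_false(identical(readLines(fa), readLines(fc)))
  ## the generator leaves the global RNG state untouched
  set.seed(1); before <- .Random.seed
  invisible(random_instance(4, 1, seed = 9))
  expect_identical(before, .Random.seed)
})

test_that("zero edge density freezes the whole network", {
  inst <- random_instance(5, 1, max_inputs = 3, edge_density = 0,
                          tau = 3, seed = 13)
  expect_equal(igraph::ecount(dependency_graph(inst$network)), 0)
  fz <- frozen_nodes(inst$network, inst$problem$initial)
  expect_setequal(fz$node, inst$network$internal)
  ## solvable iff the uncontrolled trajectory matches the target
  traj <- bn_simulate(inst$network, inst$problem$initial,
                      matrix(0L, 3, 1, dimnames = list(NULL, "u1")))
  expect_equal(solve_control(inst$problem)$solvable,
               all(traj[4, ] == inst$problem$desired))
})

test_that("the generator achieves requested cycle sizes and mixes outcomes", {
  set.seed(2)
  solvable <- logical(60)
  for (i in 1:60) {
    inst <- random_instance(6, 2, max_inputs = 3, edge_density = 0.6,
                            target_largest_scc = 3, tau = 3, seed = 5000 + i)
    if (i <= 10) expect_gte(inst$largest_scc, 3)
    solvable[i] <- brute_force_solve(inst$problem)$decision
  }
  expect_gt(mean(solvable), 0)
  expect_lt(mean(solvable), 1)
})

test_that("infeasible generator requests error cleanly", {
  expect_error(random_instance(3, 1, target_largest_scc = 4, seed = 1),
               "cannot exceed")
})
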