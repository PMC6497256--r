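test_that("candidate enumeration for a free external follows binary counting", {
  cands <- enumerate_component_sequences(fig6_network(), "u", tau = 3,
                                         initial = fig6_initial())
  expect_length(cands, 16)
  expect_equal(unname(cands[[1]]["u", ]), c(0L, 0L, 0L, 0L))
  expect_equal(unname(cands[[2]]["u", ]), c(1L, 0L, 0L, 0L))  # t = 0 is LSB
  expect_equal(unname(cands[[3]]["u", ]), c(0L, 1L, 0L, 0L))
  expect_equal(unname(cands[[16]]["u", ]), c(1L, 1L, 1L, 1L))
  ## all 16 distinct
  keys <- vapply(cands, function(cc) paste(cc["u", ], collapse = ""), "")
  expect_length(unique(keys), 16)
})

test_that("a component pinned by its context has exactly one candidate", {
  net <- fig6_network()
  g <- compute_gamma(net, fig6_initial(), tau = 3, fixed = list(u = c(1, 0, 0, 0)))
  cands <- enumerate_component_sequences(net, c("v1", "v2"), tau = 3,
                                         initial = fig6_initial(), gamma = g)
  expect_length(cands, 1)
  expect_equal(unname(cands[[1]]["v1", ]), c(0L, 1L, 0L, 1L))
  expect_equal(unname(cands[[1]]["v2", ]), c(0L, 0L, 1L, 0L))
  ## a frozen constant node also has a single candidate
  cn <- boolean_network(list(a = "1", b = "a"), external = character())
  cands2 <- enumerate_component_sequences(cn, "a", tau = 2,
                                          initial = c(a = 1, b = 0))
  expect_length(cands2, 1)
  expect_equal(unname(cands2[[1]]["a", ]), c(1L, 1L, 1L))
})

test_that("gamma_simple implements existential propagation for OR and AND", {
  net <- boolean_network(list(x = "u1", y = "u2", z = "x | y", w = "x & y"),
                         external = c("u1", "u2"))
  init <- c(x = 0, y = 0, z = 0, w = 0)
  g <- compute_gamma(net, init, tau = 2)
  ## at t = 1 both inputs can attain both values
  expect_equal(unname(gamma_simple("z", net, g, 1)), c(TRUE, TRUE))
  expect_equal(unname(gamma_simple("w", net, g, 1)), c(TRUE, TRUE))
  ## at t = 0 inputs are pinned to 0: OR and AND can only be 0 at t = 1
  expect_equal(unname(gamma_simple("z", net, g, 0)), c(TRUE, FALSE))
  expect_equal(unname(gamma_simple("w", net, g, 0)), c(TRUE, FALSE))
})

test_that("the worked-example problem solves with a verified sequence", {
  res <- solve_control(fig6_problem())
  expect_true(res$solvable)
  expect_true(res$verified)
  expect_true(verify_control(fig6_problem(), res$controls))
  ## the search fixed candidates and backtracked past infeasible ones
  expect_gt(res$stats$states_enumerated, 1)
  expect_gt(res$stats$backtracks, 0)
  expect_equal(res$stats$components, 4)
  expect_equal(res$stats$multi_node_components, 1)
})

test_that("after fixing the row-#2 candidate every node has one true gamma bit", {
  net <- fig6_network()
  g <- compute_gamma(net, fig6_initial(), tau = 3, fixed = list(u = c(1, 0, 0, 0)))
  for (v in c("u", "v1", "v2", "v3", "v4")) {
    for (t in 0:3) {
      expect_length(gamma_values(g, v, t), 1)
    }
  }
})

test_that("the Drosophila instance is solvable at tau = 6 with verification", {
  res <- solve_control(drosophila_problem())
  expect_true(res$solvable)
  expect_true(res$verified)
  expect_true(verify_control(drosophila_problem(), res$controls))
  expect_equal(res$stats$multi_node_components, 1)
})

test_that("the branching-dependency pitfall is declared unsolvable", {
  ## u feeds both a (copy) and b (negation): per-node gamma says each of
  ## a = 1 and b = 1 is attainable at t = 1, but never jointly
  net <- boolean_network(list(a = "u", b = "!u", c = "a & b"), external = "u")
  init <- c(a = 0, b = 0, c = 0)
  p <- control_problem(net, init, c(a = 1, b = 1, c = NA), tau = 1)
  g <- compute_gamma(net, init, tau = 1)
  expect_true(1L %in% gamma_values(g, "a", 1))
  expect_true(1L %in% gamma_values(g, "b", 1))
  expect_false(solve_control(p)$solvable)
  expect_false(brute_force_solve(p)$decision)
})

test_that("solver, backward DP and brute force agree on 120 random instances", {
  set.seed(2024)
  n_solvable <- 0
  for (i in 1:120) {
    n <- sample(2:8, 1)
    inst <- random_instance(n, sample(0:2, 1), max_inputs = 3,
                            edge_density = stats::runif(1, 0.25, 0.9),
                            target_largest_scc = sample(1:min(3L, n), 1),
                            tau = sample(1:5, 1), seed = 1200 + i)
    p <- inst$problem
    bf <- brute_force_solve(p)$decision
    dt <- datta_solve(p)$decision
    sv <- solve_control(p)
    expect_equal(sv$solvable, bf, info = paste("seed", 1200 + i))
    expect_equal(dt, bf, info = paste("seed", 1200 + i))
    if (sv$solvable) {
      n_solvable <- n_solvable + 1
      expect_true(sv$verified, info = paste("seed", 1200 + i))
      expect_true(verify_control(p, sv$controls), info = paste("seed", 1200 + i))
    }
  }
  expect_gt(n_solvable, 0)
  expect_lt(n_solvable, 120)
})

test_that("a desired state conflicting with a frozen node is rejected with no search", {
  net <- boolean_network(list(a = "a", b = "u & a"), external = "u")
  p <- control_problem(net, c(a = 0, b = 0), c(a = 1, b = 0), tau = 3)
  res <- solve_control(p)
  expect_false(res$solvable)
  expect_equal(res$stats$states_enumerated, 0)
})

test_that("work saved on independent chains: additive counts, multiplicative product", {
  enumerated <- integer(3)
  prods <- numeric(3)
  for (k in 1:3) {
    res <- solve_control(chain_problem(k))
    expect_true(res$solvable)
    enumerated[k] <- res$stats$states_enumerated
    prods[k] <- prod(res$stats$candidate_counts)
  }
  ## additive: cost of k chains is k times the cost of one
  expect_equal(enumerated[2], 2L * enumerated[1])
  expect_equal(enumerated[3], 3L * enumerated[1])
  ## multiplicative: the naive joint enumeration grows geometrically
  expect_equal(prods[2], prods[1]^2)
  expect_equal(prods[3], prods[1]^3)
  expect_lt(enumerated[3], prods[3])
})

test_that("don't-care horizons and control-free networks are handled", {
  ## all-don't-care: trivially solvable, all-zero controls
  net <- fig6_network()
  p <- control_problem(net, fig6_initial(),
                       c(v1 = NA, v2 = NA, v3 = NA, v4 = NA), tau = 2)
  res <- solve_control(p)
  expect_true(res$solvable)
  expect_equal(unname(res$controls[, "u"]), c(0L, 0L))
  ## m = 0: solvable iff the uncontrolled trajectory hits the target
  net0 <- boolean_network(list(a = "b", b = "!a"))
  traj <- bn_simulate(net0, c(a = 0, b = 0), NULL, tau = 2)
  p_hit <- control_problem(net0, c(a = 0, b = 0), traj[3, ], tau = 2)
  p_miss <- control_problem(net0, c(a = 0, b = 0), 1L - traj[3, ], tau = 2)
  r_hit <- solve_control(p_hit)
  expect_true(r_hit$solvable)
  expect_equal(dim(r_hit$controls), c(2L, 0L))
  expect_false(solve_control(p_miss)$solvable)
})

test_that("tau = 0 problems are decided by direct comparison", {
  net <- fig6_network()
  p_eq <- control_problem(net, fig6_initial(), fig6_initial(), tau = 0)
  expect_true(solve_control(p_eq)$solvable)
  d <- fig6_initial(); d[["v1"]] <- 1L
  p_ne <- control_problem(net, fig6_initial(), d, tau = 0)
  expect_false(solve_control(p_ne)$solvable)
})

test_that("self-loop overcounting cannot fool the solver (targeted family)", {
  ## a = u & !a can hold value 1 at consecutive steps per-node-wise, but a
  ## true trajectory cannot: a(t) = 1 forces a(t+1) = 0.  b copies a, so
  ## constraining both at the horizon probes the joint realization.
  net <- boolean_network(list(a = "u & !a", b = "a"), external = "u")
  init <- c(a = 0, b = 0)
  for (da in 0:1) for (db in 0:1) for (tau in 1:4) {
    p <- control_problem(net, init, c(a = da, b = db), tau)
    expect_equal(solve_control(p)$solvable, brute_force_solve(p)$decision,
                 info = paste(da, db, tau))
  }
})
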