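test_that("network construction validates names, functions and references", {
  expect_error(boolean_network(list(a = "b")), "undeclared")
  expect_error(boolean_network(list(a = "a", a = "a")), "duplicate")
  expect_error(boolean_network(list(a = "u"), external = c("u", "a")), "duplicate")
  expect_error(boolean_network(list(`1bad` = "1bad")), "invalid node name")
  net <- boolean_network(list(a = "u", b = "a & !u"), external = "u")
  expect_s3_class(net, "boolean_network")
  expect_equal(net$internal, c("a", "b"))
  expect_equal(net$external, "u")
})

test_that("the worked-example step semantics hold", {
  net <- fig6_network()
  ## u = 1 forces (v1, v2) = (1, 0)
  s1 <- network_step(net, c(v1 = 0, v2 = 0, v3 = 0, v4 = 0), c(u = 1))
  expect_equal(s1[["v1"]], 1L)
  expect_equal(s1[["v2"]], 0L)
  ## u = 0 exchanges v1 and v2
  s2 <- network_step(net, c(v1 = 1, v2 = 0, v3 = 0, v4 = 0), c(u = 0))
  expect_equal(s2[["v1"]], 0L)
  expect_equal(s2[["v2"]], 1L)
  ## incomplete assignments error
  expect_error(network_step(net, c(v1 = 0, v2 = 0, v3 = 0, v4 = 0)), "assign")
})

test_that("an identity network maps every state to itself", {
  net <- boolean_network(list(a = "a", b = "b", c = "c"))
  for (r in 0:7) {
    s <- stats::setNames(bitwAnd(bitwShiftR(r, 0:2), 1L), c("a", "b", "c"))
    expect_equal(unname(network_step(net, s)), unname(s))
  }
})

test_that("stepping every 3-node state yields a total transition function", {
  set.seed(7)
  net <- random_instance(3, 0, max_inputs = 2, edge_density = 0.8, seed = 11)$network
  seen <- character()
  for (r in 0:7) {
    s <- stats::setNames(bitwAnd(bitwShiftR(r, 0:2), 1L), net$internal)
    nxt <- network_step(net, s)
    expect_length(nxt, 3)
    expect_true(all(nxt %in% 0:1))
    seen <- c(seen, paste(nxt, collapse = ""))
  }
  expect_length(seen, 8)  # defined on every row of the state-transition table
})

test_that("simulate reproduces the worked-example trajectories", {
  net <- fig6_network()
  traj <- bn_simulate(net, fig6_initial(),
                      list(c(u = 1), c(u = 0), c(u = 0), c(u = 0)))
  expect_equal(unname(traj[, "v1"]), c(0L, 1L, 0L, 1L, 0L))
  expect_equal(unname(traj[, "v2"]), c(0L, 0L, 1L, 0L, 1L))
  ## v3 copies v1 with one step of delay
  expect_equal(unname(traj[1:4, "v1"]), unname(traj[2:5, "v3"]))
})

test_that("simulation is synchronous: declaration order never matters", {
  set.seed(123)
  for (i in 1:10) {
    inst <- random_instance(5, 1, max_inputs = 3, edge_density = 0.7,
                            tau = 3, seed = 200 + i)
    net <- inst$network
    perm <- sample(net$internal)
    net2 <- boolean_network(net$functions[perm], external = net$external)
    ctr <- matrix(sample(0:1, 3, replace = TRUE), ncol = 1,
                  dimnames = list(NULL, net$external))
    t1 <- bn_simulate(net, inst$problem$initial, ctr)
    t2 <- bn_simulate(net2, inst$problem$initial[perm], ctr)
    expect_equal(t1[, net$internal], t2[, net$internal])
  }
})

test_that("tau = 0 edge cases for simulate and verify", {
  net <- boolean_network(list(a = "u"), external = "u")
  traj <- bn_simulate(net, c(a = 1), NULL, tau = 0)
  expect_equal(nrow(traj), 1L)
  p_eq <- control_problem(net, c(a = 1), c(a = 1), tau = 0)
  p_ne <- control_problem(net, c(a = 1), c(a = 0), tau = 0)
  empty <- matrix(integer(), 0, 1, dimnames = list(NULL, "u"))
  expect_true(verify_control(p_eq, empty))
  expect_false(verify_control(p_ne, empty))
})

test_that("a trailing assignment at the horizon is ignored with a warning", {
  net <- fig6_network()
  p <- fig6_problem()
  ctr4 <- matrix(c(0L, 1L, 1L, 0L), ncol = 1, dimnames = list(NULL, "u"))
  expect_warning(ok <- verify_control(p, ctr4), "tau \\+ 1")
  expect_true(ok)
})

test_that("the published switch pulse steers the Drosophila network", {
  p <- drosophila_problem()
  w <- matrix(0L, 6, 3, dimnames = list(NULL, c("U1", "U2", "U3")))
  w[5, "U3"] <- 1L  # single U3 pulse at t = 4
  expect_true(verify_control(p, w))
  ## and the full trajectory ends exactly at the desired state
  traj <- bn_simulate(p$network, p$initial, w)
  expect_equal(traj[7, ], p$desired)
})
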