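test_that("the backward table marks exactly the desired state at the horizon", {
  p <- fig6_problem()  # v4 unconstrained: 2 matching states at tau
  res <- datta_solve(p)
  expect_equal(sum(res$table[, p$tau + 1L]), 2)
  p2 <- control_problem(p$network, p$initial,
                        c(v1 = 1, v2 = 0, v3 = 1, v4 = 0), p$tau)
  expect_equal(sum(datta_solve(p2)$table[, p2$tau + 1L]), 1)
})

test_that("the two-node restriction of the worked example is solvable", {
  net <- boolean_network(list(v1 = "u | (!u & v2)", v2 = "!u & v1"),
                         external = "u")
  p <- control_problem(net, c(v1 = 0, v2 = 0), c(v1 = 1, v2 = 0), tau = 3)
  res <- datta_solve(p)
  expect_true(res$decision)
  expect_true(verify_control(p, res$witness))
  ## the published trajectory's control sequence is itself a witness
  expect_true(verify_control(p, matrix(c(1L, 0L, 0L), ncol = 1,
                                       dimnames = list(NULL, "u"))))
})

test_that("backward self-consistency: every marked state has a marked successor", {
  set.seed(17)
  inst <- random_instance(4, 1, max_inputs = 3, edge_density = 0.7,
                          tau = 3, seed = 55)
  p <- inst$problem
  res <- datta_solve(p)
  net <- p$network
  for (t in seq_len(p$tau)) {
    for (s in which(res$table[, t]) - 1L) {
      state <- stats::setNames(bitwAnd(bitwShiftR(s, seq_along(net$internal) - 1L), 1L),
                               net$internal)
      succ_marked <- FALSE
      for (u in 0:1) {
        nxt <- network_step(net, state, c(u1 = u))
        code <- sum(nxt * 2^(seq_along(nxt) - 1L))
        if (res$table[code + 1L, t + 1L]) succ_marked <- TRUE
      }
      expect_true(succ_marked)
    }
  }
})

test_that("datta decision equals brute force on 60 random instances", {
  set.seed(60)
  for (i in 1:60) {
    n <- sample(2:6, 1)
    inst <- random_instance(n, sample(0:2, 1), max_inputs = 3,
                            edge_density = stats::runif(1, 0.3, 0.9),
                            target_largest_scc = sample(1:min(2L, n), 1),
                            tau = sample(1:4, 1), seed = 700 + i)
    p <- inst$problem
    expect_equal(datta_solve(p)$decision, brute_force_solve(p)$decision,
                 info = paste("seed", 700 + i))
  }
})

test_that("the size guard refuses huge tables unless forced", {
  funs <- stats::setNames(as.list(rep("0", 23)), paste0("g", 1:23))
  net <- boolean_network(funs)
  init <- stats::setNames(rep(0L, 23), net$internal)
  p <- control_problem(net, init, init, tau = 1)
  expect_error(datta_solve(p), class = "bn_resource_error")
})

test_that("the per-component table reproduces the published gamma cells", {
  dc <- datta_component(c("v1", "v2"), fig6_network(),
                        fixed_inputs = matrix(c(1, 0, 0, 0), ncol = 1,
                                              dimnames = list(NULL, "u")),
                        initial = c(v1 = 0, v2 = 0),
                        desired = c(v1 = 1, v2 = 0), tau = 3)
  expect_true(dc$feasible)
  ## exactly one feasible state per step: (0,0), (1,0), (0,1), (1,0)
  expect_equal(vapply(dc$feasible_states, nrow, integer(1)),
               stats::setNames(rep(1L, 4), paste0("t", 0:3)))
  expect_equal(unname(dc$gamma1["v1", ]), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(unname(dc$gamma0["v1", ]), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unname(dc$gamma1["v2", ]), c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(unname(dc$gamma0["v2", ]), c(TRUE, TRUE, FALSE, TRUE))
})

test_that("a conflicting desired restriction empties the feasible set", {
  ## under u fixed to all-ones, (v1, v2) is pinned to (1, 0) from t = 1
  dc <- datta_component(c("v1", "v2"), fig6_network(),
                        fixed_inputs = matrix(c(1, 1, 1, 1), ncol = 1,
                                              dimnames = list(NULL, "u")),
                        initial = c(v1 = 0, v2 = 0),
                        desired = c(v1 = 0, v2 = 1), tau = 3)
  expect_false(dc$feasible)
  expect_equal(nrow(dc$feasible_states[["t3"]]), 0L)
})

test_that("feasible sets match forward enumeration on random 3-node components", {
  set.seed(81)
  for (i in 1:20) {
    inst <- random_instance(3, 1, max_inputs = 3, edge_density = 0.8,
                            target_largest_scc = 3, tau = 3, seed = 900 + i)
    net <- inst$network
    p <- inst$problem
    mem <- net$internal
    u_traj <- sample(0:1, 4, replace = TRUE)
    dc <- datta_component(mem, net,
                          fixed_inputs = matrix(u_traj, ncol = 1,
                                                dimnames = list(NULL, "u1")),
                          initial = p$initial, desired = NULL, tau = 3)
    ## oracle: iterate the full state map under the fixed external values
    reach <- list(sum(p$initial * 2^(seq_along(mem) - 1L)))
    for (t in 1:3) {
      nxt <- unique(vapply(reach[[t]], function(code) {
        s <- stats::setNames(bitwAnd(bitwShiftR(code, seq_along(mem) - 1L), 1L), mem)
        out <- network_step(net, s, c(u1 = u_traj[t]))
        sum(out * 2^(seq_along(mem) - 1L))
      }, numeric(1)))
      reach[[t + 1L]] <- sort(nxt)
    }
    for (t in 0:3) {
      got <- sort(dc$feasible_states[[t + 1L]] %*% 2^(seq_along(mem) - 1L))
      expect_equal(as.numeric(got), as.numeric(reach[[t + 1L]]),
                   info = paste("seed", 900 + i, "t", t))
    }
  }
})
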