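#' Brute-force control oracle
#'
#' Enumerates every control sequence of length tau (all 2^(m*tau) of them),
#' simulates each one forward, and counts those that reach the desired
#' state. Correct by construction; used throughout as the independent check
#' on the decomposition solver and the backward dynamic program. Sequences
#' are enumerated in time-major binary order: sequence index k assigns
#' external j at time t the bit of k at position m*t + (j - 1), so the
#' all-zero sequence comes first and the reported witness is the first
#' success in that order.
#'
#' @param problem a [control_problem()].
#' @param max_sequences refuse instances with more than this many control
#'   sequences (default 2^24).
#' @return List with `decision` (logical), `witness` (tau x m control matrix
#'   or NULL) and `count_solutions`.
#' @examples
#' brute_force_solve(fig6_problem())
#' @export
brute_force_solve <- function(problem, max_sequences = 2^24) {
  stopifnot(inherits(problem, "control_problem"))
  net <- problem$network
  m <- length(net$external)
  tau <- problem$tau
  n_seq <- 2^(m * tau)
  if (n_seq > max_sequences) {
    stop(bn_resource_error(sprintf(
      "brute force would enumerate 2^%d control sequences (cap %g)",
      m * tau, max_sequences)))
  }
  compiled <- compile_network(net)
  s0 <- encode_bits(problem$initial, net$internal)
  k <- seq_len(n_seq) - 1
  S <- rep(s0, n_seq)
  if (tau > 0L) {
    for (t in 0:(tau - 1L)) {
      U <- (k %/% 2^(m * t)) %% 2^m
      S <- step_encoded(compiled, S, U)
    }
  }
  ok <- rep(TRUE, n_seq)
  for (j in which(!is.na(problem$desired))) {
    bit <- (S %/% 2^(j - 1)) %% 2
    ok <- ok & (bit == problem$desired[j])
  }
  count <- sum(ok)
  witness <- NULL
  if (count > 0) {
    kw <- k[which(ok)[1L]]
    witness <- matrix(0L, nrow = tau, ncol = m,
                      dimnames = list(NULL, net$external))
    if (tau > 0L && m > 0L) {
      for (t in 0:(tau - 1L)) {
        witness[t + 1L, ] <- decode_bits((kw %/% 2^(m * t)) %% 2^m, net$external)
      }
    }
  }
  list(decision = count > 0, witness = witness, count_solutions = count)
}

#' Generate a seeded random control instance
#'
#' Draws a random Boolean network and control problem, reproducibly from the
#' seed (the global RNG state is saved and restored). Every internal node
#' receives a random AND/OR/NOT tree over a sampled input set; the number of
#' inputs per node is binomial with `max_inputs` trials and success
#' probability `edge_density` (zero inputs gives a random constant
#' function). When `target_largest_scc > 1` the first that many internal
#' nodes are wired into a cycle so the instance contains a multi-node
#' component of at least that size; the achieved largest-SCC size is
#' reported. The initial state is uniform; with probability 1/2 the desired
#' state is read off a simulated trajectory under random controls
#' (guaranteeing solvability), otherwise it is uniform, so a batch of
#' instances mixes solvable and unsolvable cases.
#'
#' @param n_internal,n_external node counts.
#' @param max_inputs maximum inputs per update function.
#' @param edge_density per-input inclusion probability in 0..1.
#' @param target_largest_scc wire the first this-many internal nodes into a
#'   cycle (1 = no forced cycle). Must not exceed `n_internal`.
#' @param tau control horizon.
#' @param seed integer seed; identical seeds reproduce identical instances.
#' @return List with `network`, `problem`, `largest_scc` (achieved size) and
#'   `scc_sizes`.
#' @export
random_instance <- function(n_internal, n_external, max_inputs = 3L,
                            edge_density = 0.5, target_largest_scc = 1L,
                            tau = 4L, seed) {
  stopifnot(n_internal >= 1L, n_external >= 0L, max_inputs >= 0L,
            edge_density >= 0, edge_density <= 1)
  if (target_largest_scc > n_internal) {
    stop("target_largest_scc cannot exceed n_internal", call. = FALSE)
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  internal <- paste0("v", seq_len(n_internal))
  external <- if (n_external > 0L) paste0("u", seq_len(n_external)) else character()
  all_names <- c(internal, external)
  cycle <- if (target_largest_scc >= 2L) seq_len(target_largest_scc) else integer()

  rand_tree <- function(inputs) {
    if (length(inputs) == 0L) return(bexpr_const(sample(0:1, 1L)))
    inputs <- sample(inputs)
    leaf <- function(nm) {
      e <- bexpr_var(nm)
      if (stats::runif(1) < 0.35) bexpr_not(e) else e
    }
    expr <- leaf(inputs[1L])
    for (nm in inputs[-1L]) {
      expr <- if (stats::runif(1) < 0.5) bexpr_and(expr, leaf(nm))
              else bexpr_or(expr, leaf(nm))
    }
    expr
  }

  funs <- vector("list", n_internal)
  names(funs) <- internal
  for (i in seq_len(n_internal)) {
    k <- stats::rbinom(1L, max_inputs, edge_density)
    forced <- if (i %in% cycle) {
      prev <- cycle[which(cycle == i) - 1L]
      if (length(prev) == 0L) prev <- cycle[length(cycle)]
      internal[prev]
    } else character()
    pool <- setdiff(all_names, forced)
    extra <- sample(pool, min(max(k - length(forced), 0L), length(pool)))
    funs[[i]] <- rand_tree(c(forced, extra))
  }
  net <- boolean_network(funs, external = external)

  initial <- stats::setNames(sample(0:1, n_internal, replace = TRUE), internal)
  desired <- if (stats::runif(1) < 0.5) {
    ctrl <- matrix(sample(0:1, tau * n_external, replace = TRUE),
                   nrow = tau, ncol = n_external,
                   dimnames = list(NULL, external))
    traj <- bn_simulate(net, initial, ctrl, tau = tau)
    traj[tau + 1L, ]
  } else {
    stats::setNames(sample(0:1, n_internal, replace = TRUE), internal)
  }

  sizes <- sort(vapply(decompose_network(net), function(cc) length(cc$members),
                       integer(1)), decreasing = TRUE)
  list(network = net,
       problem = control_problem(net, initial, desired, tau),
       largest_scc = sizes[1L],
       scc_sizes = sizes)
}
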