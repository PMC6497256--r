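#' Full-network backward dynamic program (Datta-style baseline)
#'
#' Fills the table `D(state, t)` backward from the horizon: at t = tau exactly
#' the states matching the desired restriction are marked; at earlier t a
#' state is marked iff some external assignment sends it to a marked state at
#' t + 1. The problem is solvable iff the initial state is marked at t = 0.
#' The table enumerates all 2^n internal states per time step and all 2^m
#' external assignments per backward step, so it is exponential in the
#' network size; it serves as the exact baseline and as the per-component
#' engine when restricted to one strongly connected component.
#'
#' @param problem a [control_problem()].
#' @param max_nodes refuse networks with more internal nodes than this
#'   (default 22) unless `force = TRUE`; the table has 2^n rows.
#' @param force proceed past the size guard.
#' @return An object of class `datta_result`: list with `decision` (logical),
#'   `table` (2^n x (tau + 1) logical matrix, row r = encoded state r - 1),
#'   `witness` (a tau x m control matrix extracted greedily from the table
#'   when solvable, preferring 0 bits) and `problem`.
#' @examples
#' p <- fig6_problem()
#' datta_solve(p)$decision
#' @export
datta_solve <- function(problem, max_nodes = 22L, force = FALSE) {
  stopifnot(inherits(problem, "control_problem"))
  net <- problem$network
  n <- length(net$internal)
  m <- length(net$external)
  tau <- problem$tau
  if (n > max_nodes && !force) {
    stop(bn_resource_error(sprintf(
      "datta_solve table would have 2^%d rows; raise max_nodes or use force = TRUE", n)))
  }
  compiled <- compile_network(net)
  n_states <- 2^n
  states <- seq_len(n_states) - 1
  ## next-state map per external assignment
  n_ctrl <- 2^m
  nxt <- matrix(0, nrow = n_states, ncol = n_ctrl)
  for (u in seq_len(n_ctrl) - 1L) {
    nxt[, u + 1L] <- step_encoded(compiled, states, u)
  }

  D <- matrix(FALSE, nrow = n_states, ncol = tau + 1L,
              dimnames = list(NULL, paste0("t", 0:tau)))
  cons <- !is.na(problem$desired)
  didx <- which(cons)
  match_desired <- rep(TRUE, n_states)
  for (j in didx) {
    bit <- (states %/% 2^(j - 1)) %% 2
    match_desired <- match_desired & (bit == problem$desired[j])
  }
  D[, tau + 1L] <- match_desired
  if (tau > 0L) {
    for (t in tau:1L) {
      reach <- rep(FALSE, n_states)
      for (u in seq_len(n_ctrl)) {
        reach <- reach | D[nxt[, u] + 1L, t + 1L]
      }
      D[, t] <- reach
    }
  }

  s0 <- encode_bits(problem$initial, net$internal)
  decision <- unname(D[s0 + 1L, 1L])

  witness <- NULL
  if (decision && tau >= 0L) {
    witness <- matrix(0L, nrow = tau, ncol = m,
                      dimnames = list(NULL, net$external))
    s <- s0
    if (tau > 0L) for (t in seq_len(tau)) {
      for (u in seq_len(n_ctrl) - 1L) {
        s2 <- nxt[s + 1L, u + 1L]
        if (D[s2 + 1L, t + 1L]) {
          if (m > 0L) witness[t, ] <- decode_bits(u, net$external)
          s <- s2
          break
        }
      }
    }
  }

  structure(list(decision = decision, table = D, witness = witness,
                 problem = problem),
            class = "datta_result")
}

#' @export
print.datta_result <- function(x, ...) {
  cat(sprintf("Backward DP over %d states, tau = %d: %s\n",
              nrow(x$table), x$problem$tau,
              if (x$decision) "solvable" else "no control sequence exists"))
  cat(sprintf("  marked states per t: %s\n",
              paste(colSums(x$table), collapse = ", ")))
  invisible(x)
}

#' Backward/forward dynamic program restricted to one component
#'
#' Runs the embedded dynamic program on the members of a single strongly
#' connected component, treating the already-fixed upstream trajectories as
#' time-indexed constants. Returns, for every t, the member states that are
#' forward-reachable from the initial restriction and backward-consistent
#' with the desired restriction at the horizon, plus the per-member gamma
#' bits they witness.
#'
#' @param members character vector: the component's member nodes.
#' @param network a [boolean_network()].
#' @param fixed_inputs a (tau + 1) x k matrix (or data.frame) of bits,
#'   columns named by the upstream nodes feeding the component, row t + 1 =
#'   values at time t. All upstream inputs of the members must be covered.
#' @param initial named bit vector restricting the members' state at t = 0
#'   (internal members; may be NULL for a free start).
#' @param desired named bit vector restricting members at t = tau, or NULL
#'   for unconstrained.
#' @param tau horizon.
#' @return List with `feasible_states` (per-t list of matrices, one row per
#'   feasible member state), `gamma0`/`gamma1` (member x (tau + 1) logical
#'   matrices) and `feasible` (TRUE iff some state survives at t = tau).
#' @export
datta_component <- function(members, network, fixed_inputs = NULL,
                            initial = NULL, desired = NULL, tau) {
  tau <- as.integer(tau)
  fixed_inputs <- if (is.null(fixed_inputs)) {
    matrix(integer(), nrow = tau + 1L, ncol = 0L)
  } else as.matrix(fixed_inputs)
  if (ncol(fixed_inputs) > 0L && nrow(fixed_inputs) < tau) {
    stop("fixed_inputs must supply upstream values for t = 0..tau-1", call. = FALSE)
  }
  allowed <- function(node, t) {
    if (node %in% colnames(fixed_inputs)) {
      as.integer(fixed_inputs[t + 1L, node])
    } else if (node %in% network$external) {
      c(0L, 1L)  # free external input
    } else {
      stop(sprintf("upstream trajectory for internal node '%s' not supplied", node),
           call. = FALSE)
    }
  }
  reach <- component_reach(network, members, tau, init = initial,
                           desired = desired, allowed = allowed)
  g0 <- matrix(FALSE, nrow = reach$w, ncol = tau + 1L,
               dimnames = list(reach$members, paste0("t", 0:tau)))
  g1 <- g0
  feas <- vector("list", tau + 1L)
  names(feas) <- paste0("t", 0:tau)
  for (t in 0:tau) {
    states <- reach$feasible[[t + 1L]]
    sm <- matrix(0L, nrow = length(states), ncol = reach$w,
                 dimnames = list(NULL, reach$members))
    for (j in seq_len(reach$w)) {
      bits <- bitwAnd(bitwShiftR(states, j - 1L), 1L)
      sm[, j] <- bits
      g0[j, t + 1L] <- any(bits == 0L)
      g1[j, t + 1L] <- any(bits == 1L)
    }
    feas[[t + 1L]] <- sm
  }
  list(feasible_states = feas, gamma0 = g0, gamma1 = g1,
       feasible = length(reach$feasible[[tau + 1L]]) > 0L)
}
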