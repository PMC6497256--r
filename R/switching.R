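#' Minimal-switching control strategy
#'
#' Among all valid control sequences, finds one minimizing the total number
#' of control-node switches — adjacent-time value changes summed over the
#' external nodes, `sum_u sum_{t=1..tau-1} [u(t) != u(t-1)]`. Ties are
#' broken lexicographically on the concatenated bit-string (u^0's bits in
#' external declaration order, then u^1's, ...), so the result is unique
#' and reproducible.
#'
#' The optimum is computed by an exact backward dynamic program over
#' (internal state, previous control assignment, time) — cost-to-go =
#' minimal future switches — followed by a forward walk that picks, at each
#' step, the lexicographically smallest assignment attaining the optimal
#' residual cost. The table has 2^n * 2^m entries per time step, so the
#' method carries its own size guard.
#'
#' @param problem a [control_problem()].
#' @param max_nodes refuse problems with more internal nodes than this
#'   (default 18) unless `force = TRUE`.
#' @param force proceed past the size guard.
#' @return A `bn_control_result` with the extra field `switch_count`
#'   (NULL when unsolvable).
#' @examples
#' res <- minimize_switching(fig6_problem())
#' res$switch_count
#' @export
minimize_switching <- function(problem, max_nodes = 18L, force = FALSE) {
  stopifnot(inherits(problem, "control_problem"))
  net <- problem$network
  n <- length(net$internal)
  m <- length(net$external)
  tau <- problem$tau
  if (n > max_nodes && !force) {
    stop(bn_resource_error(sprintf(
      "minimize_switching table would have 2^%d x 2^%d entries; use force = TRUE",
      n, m)))
  }
  compiled <- compile_network(net)
  n_states <- 2^n
  n_ctrl <- 2^m
  states <- seq_len(n_states) - 1

  nxt <- matrix(0, nrow = n_states, ncol = n_ctrl)
  for (u in seq_len(n_ctrl) - 1L) nxt[, u + 1L] <- step_encoded(compiled, states, u)

  ham <- outer(seq_len(n_ctrl) - 1L, seq_len(n_ctrl) - 1L, function(a, b) {
    vapply(bitwXor(a, b), function(x) sum(bitwAnd(bitwShiftR(x, 0:(max(m, 1) - 1L)), 1L)),
           integer(1))
  })
  ## lexicographic order of control assignments: first declared external is
  ## the most significant position of the concatenated bit-string
  lex_rank <- vapply(seq_len(n_ctrl) - 1L, function(u) {
    bits <- bitwAnd(bitwShiftR(u, seq_len(max(m, 1L)) - 1L), 1L)[seq_len(m)]
    if (m == 0L) 0 else sum(bits * 2^(m - seq_len(m)))
  }, numeric(1))
  u_lex_order <- order(lex_rank)

  cons <- which(!is.na(problem$desired))
  match_desired <- rep(TRUE, n_states)
  for (j in cons) {
    bit <- (states %/% 2^(j - 1)) %% 2
    match_desired <- match_desired & (bit == problem$desired[j])
  }

  s0 <- encode_bits(problem$initial, net$internal)
  mk_result <- function(solvable, controls = NULL, verified = FALSE,
                        switch_count = NULL) {
    out <- structure(list(solvable = solvable, controls = controls,
                          verified = verified,
                          stats = list(states_enumerated = n_states * n_ctrl * tau,
                                       backtracks = 0,
                                       components = NA_integer_,
                                       multi_node_components = NA_integer_,
                                       candidate_counts = numeric(0)),
                          problem = problem),
                     class = "bn_control_result")
    out$switch_count <- switch_count
    out
  }

  if (tau == 0L) {
    ok <- match_desired[s0 + 1L]
    ctr <- matrix(integer(), nrow = 0L, ncol = m, dimnames = list(NULL, net$external))
    return(mk_result(ok, controls = if (ok) ctr, verified = ok,
                     switch_count = if (ok) 0L))
  }

  ## g[[t]][s, p]: minimal switches over steps t..tau-1 given state s at
  ## time t and control p applied at t - 1 (t = 1..tau)
  g <- vector("list", tau + 1L)
  g[[tau + 1L]] <- matrix(ifelse(match_desired, 0, Inf),
                          nrow = n_states, ncol = n_ctrl)
  for (t in tau:1L) {
    V <- matrix(Inf, nrow = n_states, ncol = n_ctrl)  # cost if u chosen at t
    for (u in seq_len(n_ctrl)) {
      V[, u] <- g[[t + 1L]][nxt[, u] + 1L, u]
    }
    gt <- matrix(Inf, nrow = n_states, ncol = n_ctrl)
    for (p in seq_len(n_ctrl)) {
      best <- rep(Inf, n_states)
      for (u in seq_len(n_ctrl)) {
        best <- pmin(best, ham[p, u] + V[, u])
      }
      gt[, p] <- best
    }
    g[[t]] <- gt
  }

  ## no switch cost at t = 0
  total <- min(vapply(seq_len(n_ctrl), function(u) {
    g[[2L]][nxt[s0 + 1L, u] + 1L, u]
  }, numeric(1)))
  if (!is.finite(total)) return(mk_result(FALSE))

  controls <- matrix(0L, nrow = tau, ncol = m, dimnames = list(NULL, net$external))
  s <- s0
  prev <- NA_integer_
  residual <- total
  for (t in seq_len(tau)) {
    for (u in u_lex_order) {
      cost_here <- if (t == 1L) 0 else ham[prev, u]
      s2 <- nxt[s + 1L, u]
      if (cost_here + g[[t + 1L]][s2 + 1L, u] == residual) {
        if (m > 0L) controls[t, ] <- decode_bits(u - 1L, net$external)
        residual <- residual - cost_here
        s <- s2
        prev <- u
        break
      }
    }
  }

  stopifnot(verify_control(problem, controls))
  mk_result(TRUE, controls = controls, verified = TRUE,
            switch_count = as.integer(total))
}

#' Count the switches of a control sequence
#'
#' @param controls a tau x m control matrix.
#' @return Integer: total adjacent-time value changes over all externals.
#' @export
switch_count <- function(controls) {
  controls <- as.matrix(controls)
  if (nrow(controls) < 2L) return(0L)
  sum(controls[-1L, , drop = FALSE] != controls[-nrow(controls), , drop = FALSE])
}
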