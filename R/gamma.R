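#' Per-node, per-time reachability (gamma) tables
#'
#' For each node v, bit b and time step t, the gamma table records whether
#' the external nodes can be assigned so that v holds value b at time t,
#' given everything fixed so far. Internal nodes start as a singleton at
#' t = 0 (their initial value); external nodes start with both bits true at
#' every step; fixing a component to one candidate trajectory collapses its
#' members to singletons.
#'
#' @name gamma-tables
NULL

new_gamma <- function(network, initial, tau) {
  all_names <- c(network$internal, network$external)
  g0 <- matrix(FALSE, nrow = length(all_names), ncol = tau + 1L,
               dimnames = list(all_names, paste0("t", 0:tau)))
  g1 <- g0
  ## external nodes: both values available at every step until fixed
  if (length(network$external)) {
    g0[network$external, ] <- TRUE
    g1[network$external, ] <- TRUE
  }
  ## internal nodes: singleton at t = 0
  for (v in network$internal) {
    if (initial[[v]] == 1L) g1[v, 1L] <- TRUE else g0[v, 1L] <- TRUE
  }
  structure(list(g0 = g0, g1 = g1, nodes = all_names, tau = tau),
            class = "gamma_table")
}

#' @export
print.gamma_table <- function(x, ...) {
  cat(sprintf("gamma table: %d node(s), t = 0..%d\n", length(x$nodes), x$tau))
  sym <- matrix(".", nrow = nrow(x$g0), ncol = ncol(x$g0),
                dimnames = dimnames(x$g0))
  sym[x$g0 & !x$g1] <- "0"
  sym[!x$g0 & x$g1] <- "1"
  sym[x$g0 & x$g1] <- "*"
  print(as.data.frame(sym))
  cat("(0/1 = only that value attainable, * = both, . = neither)\n")
  invisible(x)
}

set_gamma_fixed <- function(gamma, node, values) {
  stopifnot(length(values) == gamma$tau + 1L)
  gamma$g0[node, ] <- values == 0L
  gamma$g1[node, ] <- values == 1L
  gamma
}

set_gamma_sets <- function(gamma, reach) {
  ## fill member rows from the feasible state sets of a component_reach
  for (t in 0:reach$tau) {
    states <- reach$feasible[[t + 1L]]
    for (j in seq_len(reach$w)) {
      bits <- bitwAnd(bitwShiftR(states, j - 1L), 1L)
      gamma$g0[reach$members[j], t + 1L] <- any(bits == 0L)
      gamma$g1[reach$members[j], t + 1L] <- any(bits == 1L)
    }
  }
  gamma
}

#' One forward gamma step for a single node
#'
#' Computes the pair (gamma^0, gamma^1) of node `node` at time t + 1 by
#' existential quantification over the input-value combinations admitted by
#' the inputs' gamma bits at time t: value b is attainable at t + 1 iff some
#' combination of admissible input values makes the update function equal b.
#' This is the sequential fill used for non-branching single-node components.
#'
#' @param node an internal node name.
#' @param network a [boolean_network()].
#' @param gamma a `gamma_table` whose entries at time `t` are filled for all
#'   inputs of `node`.
#' @param t the time step whose values feed the computation (result is for
#'   t + 1).
#' @return Logical vector `c(g0, g1)`.
#' @export
gamma_simple <- function(node, network, gamma, t) {
  stopifnot(node %in% network$internal, t >= 0L, t < gamma$tau)
  f <- network$functions[[node]]
  vars <- expression_vars(f)
  sets <- lapply(vars, function(u) gamma_allowed(gamma, u, t))
  if (any(lengths(sets) == 0L)) {
    stop(sprintf("gamma entries for input(s) of '%s' at t = %d are empty", node, t),
         call. = FALSE)
  }
  g0 <- FALSE; g1 <- FALSE
  grid <- if (length(vars)) {
    do.call(expand.grid, c(stats::setNames(sets, vars), KEEP.OUT.ATTRS = FALSE))
  } else data.frame(row.names = 1L)
  for (r in seq_len(max(nrow(grid), 1L))) {
    asn <- if (length(vars)) stats::setNames(as.integer(grid[r, ]), vars) else c()
    if (evaluate_expression(f, asn) == 1L) g1 <- TRUE else g0 <- TRUE
    if (g0 && g1) break
  }
  c(g0 = g0, g1 = g1)
}

#' Compute gamma tables over the whole network
#'
#' Processes strongly connected components in topological order: components
#' whose trajectory is supplied in `fixed` collapse to singletons;
#' single-node non-branching components are filled sequentially with
#' [gamma_simple()]; the remaining (hard) components are analysed with the
#' embedded per-component dynamic program, their gamma rows reflecting the
#' states that are forward-reachable and backward-consistent with the
#' desired restriction (when `desired` is given).
#'
#' This is the diagnostic/reporting view of the solver's forward pass; the
#' full solver additionally enumerates and fixes candidate trajectories for
#' hard components with backtracking.
#'
#' @param network a [boolean_network()].
#' @param initial named bit vector over internal nodes at t = 0.
#' @param tau horizon.
#' @param desired optional named bit vector (NA = don't care) constraining
#'   internal nodes at t = tau.
#' @param fixed named list: node name -> integer vector of length tau + 1
#'   giving a fixed trajectory for that node (all members of a component
#'   must be fixed together).
#' @return A `gamma_table`.
#' @examples
#' compute_gamma(fig6_network(), fig6_initial(), tau = 3,
#'               desired = c(v1 = 1, v2 = 0, v3 = 1, v4 = NA),
#'               fixed = list(u = c(1, 0, 0, 0)))
#' @export
compute_gamma <- function(network, initial, tau, desired = NULL, fixed = list()) {
  initial <- check_state(initial, network$internal, "initial state")
  if (!is.null(desired)) {
    desired <- check_state(desired, network$internal, "desired state", allow_na = TRUE)
  }
  tau <- as.integer(tau)
  compiled <- compile_network(network)
  dec <- decompose_network(network)
  gamma <- new_gamma(network, initial, tau)

  for (nm in names(fixed)) {
    stopifnot(nm %in% gamma$nodes, length(fixed[[nm]]) == tau + 1L)
  }

  for (comp in dec) {
    mem <- comp$members
    if (all(mem %in% names(fixed))) {
      for (v in mem) gamma <- set_gamma_fixed(gamma, v, as.integer(fixed[[v]]))
      next
    }
    if (any(mem %in% names(fixed))) {
      stop("all members of a component must be fixed together: ",
           paste(mem, collapse = ", "), call. = FALSE)
    }
    if (comp$category == "SIMPLE_NONBRANCHING") {
      v <- mem
      if (v %in% network$external) next  # both bits already true
      if (tau > 0L) for (t in 0:(tau - 1L)) {
        g <- gamma_simple(v, network, gamma, t)
        gamma$g0[v, t + 2L] <- g[["g0"]]
        gamma$g1[v, t + 2L] <- g[["g1"]]
      }
    } else {
      cons <- if (!is.null(desired)) {
        dd <- desired[intersect(mem, network$internal)]
        dd <- dd[!is.na(dd)]
        if (length(dd)) dd else NULL
      } else NULL
      init_r <- {
        iv <- initial[intersect(mem, network$internal)]
        if (length(iv)) iv else NULL
      }
      reach <- component_reach(network, mem, tau, init = init_r, desired = cons,
                               allowed = function(node, t) gamma_allowed(gamma, node, t),
                               compiled = compiled)
      gamma <- set_gamma_sets(gamma, reach)
    }
  }
  gamma
}

#' Attainable values of a node at a time step
#'
#' @param gamma a `gamma_table`.
#' @param node a node name.
#' @param t time step in 0..tau.
#' @return Integer vector: subset of `c(0, 1)`.
#' @export
gamma_values <- function(gamma, node, t) gamma_allowed(gamma, node, t)
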