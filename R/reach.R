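## Per-component reachability engine.
##
## A component (one or more member nodes) evolves under a time-inhomogeneous
## transition relation: member updates read other members at time t plus
## upstream nodes whose per-time admissible values are supplied by the caller
## (singletons for already-fixed upstream trajectories, {0,1} for free
## external inputs, or whatever the current gamma table admits).  External
## member nodes have no dynamics: they may take either value at every step.
##
## component_reach computes, for t = 0..tau, the set of member states that
## are forward-reachable from the initial restriction AND backward-consistent
## with the desired restriction at tau (intersecting with forward
## reachability prunes states the backward table alone would keep), together
## with the surviving per-step transition edges.  Candidate trajectories are
## paths through the surviving edges.

gamma_allowed <- function(gamma, node, t) {
  col <- t + 1L
  vals <- integer(0)
  if (gamma$g0[node, col]) vals <- 0L
  if (gamma$g1[node, col]) vals <- c(vals, 1L)
  vals
}

## enumerate all upstream assignments: list of named integer vectors
upstream_combos <- function(upstream, allowed, t) {
  if (length(upstream) == 0L) return(list(stats::setNames(integer(0), character(0))))
  sets <- lapply(upstream, function(u) {
    vals <- allowed(u, t)
    if (length(vals) == 0L) return(NULL)
    vals
  })
  if (any(vapply(sets, is.null, logical(1)))) return(list())
  grid <- do.call(expand.grid, c(stats::setNames(sets, upstream),
                                 KEEP.OUT.ATTRS = FALSE))
  lapply(seq_len(nrow(grid)), function(r) {
    stats::setNames(as.integer(grid[r, ]), upstream)
  })
}

component_reach <- function(network, members, tau,
                            init = NULL, desired = NULL,
                            allowed = function(node, t) c(0L, 1L),
                            compiled = NULL) {
  all_names <- c(network$internal, network$external)
  members <- members[order(match(members, all_names))]
  w <- length(members)
  is_internal <- members %in% network$internal
  if (is.null(compiled)) compiled <- compile_network(network)

  ## mini truth tables for internal members, inputs in (member?, name) terms
  minis <- lapply(members, function(v) {
    if (!(v %in% network$internal)) return(NULL)
    nd <- compiled$nodes[[v]]
    list(inputs = nd$inputs, tt = nd$tt,
         member_pos = match(nd$inputs, members))  # NA for upstream inputs
  })
  upstream <- setdiff(unique(unlist(lapply(minis, function(x) x$inputs))), members)
  upstream <- upstream[order(match(upstream, all_names))]

  member_bits <- function(code) bitwAnd(bitwShiftR(code, seq_len(w) - 1L), 1L)

  ## initial state set
  init_states <- if (is.null(init)) {
    seq_len(bitwShiftL(1L, w)) - 1L
  } else {
    fixed_idx <- match(names(init), members)
    stopifnot(!anyNA(fixed_idx))
    free_idx <- setdiff(seq_len(w), fixed_idx)
    base <- sum(as.integer(init) * 2^(fixed_idx - 1L))
    vapply(seq_len(bitwShiftL(1L, length(free_idx))) - 1L, function(r) {
      base + sum(bitwAnd(bitwShiftR(r, seq_along(free_idx) - 1L), 1L) *
                   2^(free_idx - 1L))
    }, numeric(1))
  }
  init_states <- sort(unique(as.integer(init_states)))

  F <- vector("list", tau + 1L)
  edges <- vector("list", max(tau, 0L))
  F[[1L]] <- init_states
  if (tau > 0L) {
    for (t in 0:(tau - 1L)) {
      combos <- upstream_combos(upstream, allowed, t)
      from <- integer(0); to <- integer(0)
      for (s in F[[t + 1L]]) {
        bits <- member_bits(s)
        succ <- integer(0)
        for (cmb in combos) {
          nxt <- 0L
          for (j in seq_len(w)) {
            if (!is_internal[j]) next
            mini <- minis[[j]]
            idx <- 0L
            for (p in seq_along(mini$inputs)) {
              mp <- mini$member_pos[p]
              b <- if (!is.na(mp)) bits[mp] else cmb[[mini$inputs[p]]]
              idx <- idx + b * bitwShiftL(1L, p - 1L)
            }
            nxt <- nxt + mini$tt[idx + 1L] * bitwShiftL(1L, j - 1L)
          }
          succ <- c(succ, nxt)
        }
        succ <- unique(succ)
        ## external members branch freely over both values
        for (j in which(!is_internal)) {
          succ <- unique(c(succ, succ + bitwShiftL(1L, j - 1L)))
        }
        if (length(combos)) {
          from <- c(from, rep(s, length(succ)))
          to <- c(to, succ)
        }
      }
      keep <- !duplicated(cbind(from, to))
      edges[[t + 1L]] <- cbind(from = from[keep], to = to[keep])
      F[[t + 2L]] <- sort(unique(to))
    }
  }

  ## backward filter against the desired restriction at tau
  ok <- vector("list", tau + 1L)
  final <- F[[tau + 1L]]
  if (!is.null(desired) && length(desired)) {
    didx <- match(names(desired), members)
    stopifnot(!anyNA(didx))
    match_desired <- vapply(final, function(s) {
      all(member_bits(s)[didx] == as.integer(desired))
    }, logical(1))
    final <- final[match_desired]
  }
  ok[[tau + 1L]] <- final
  if (tau > 0L) {
    for (t in tau:1L) {
      e <- edges[[t]]
      keep <- e[, "to"] %in% ok[[t + 1L]]
      e <- e[keep, , drop = FALSE]
      ok[[t]] <- intersect(F[[t]], unique(e[, "from"]))
      ## also drop edges leaving states that are themselves unreachable later
      edges[[t]] <- e
    }
    for (t in seq_len(tau)) {
      e <- edges[[t]]
      edges[[t]] <- e[e[, "from"] %in% ok[[t]], , drop = FALSE]
    }
  }

  list(members = members, w = w, is_internal = is_internal,
       upstream = upstream, feasible = ok, edges = edges, tau = tau,
       minis = minis)
}

## all trajectories (paths through the surviving edges), ordered by the key
## sum_t state_t * (2^w)^t  — i.e. binary/(2^w)-ary counting with t = 0 as
## the least significant digit, which for a single free external node
## reproduces the documented enumeration order (all-zero sequence first,
## then the sequence with a single 1 at t = 0, ...).
component_paths <- function(reach, max_candidates = 65536L) {
  tau <- reach$tau
  if (length(reach$feasible[[tau + 1L]]) == 0L) return(list())
  paths <- list()
  walk <- function(t, prefix) {
    if (t == tau) {
      paths[[length(paths) + 1L]] <<- prefix
      if (length(paths) > max_candidates) {
        stop(bn_resource_error(sprintf(
          "component candidate enumeration exceeded %d trajectories", max_candidates)))
      }
      return()
    }
    e <- reach$edges[[t + 1L]]
    succ <- sort(unique(e[e[, "from"] == prefix[t + 1L], "to"]))
    for (s in succ) walk(t + 1L, c(prefix, s))
  }
  for (s0 in sort(reach$feasible[[1L]])) walk(0L, s0)
  base <- 2^reach$w
  keys <- vapply(paths, function(p) sum(p * base^(0:tau)), numeric(1))
  paths[order(keys)]
}

## decode a path (encoded member states per t) into a members x (tau+1) bit matrix
path_to_trajectory <- function(reach, path) {
  w <- reach$w
  out <- vapply(path, function(s) bitwAnd(bitwShiftR(s, seq_len(w) - 1L), 1L),
                integer(w))
  out <- matrix(out, nrow = w,
                dimnames = list(reach$members, paste0("t", seq_along(path) - 1L)))
  out
}

bn_resource_error <- function(msg) {
  structure(class = c("bn_resource_error", "error", "condition"),
            list(message = msg, call = NULL))
}

bn_usage_error <- function(msg) {
  structure(class = c("bn_usage_error", "error", "condition"),
            list(message = msg, call = NULL))
}
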