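#' Solve a Boolean network control problem by SCC decomposition
#'
#' The main algorithm. The dependency graph is partitioned into strongly
#' connected components, processed in topological order:
#'
#' * single-node non-branching ("simple") components fill their per-node
#'   gamma reachability bits sequentially, with early rejection as soon as a
#'   component cannot meet its horizon constraint;
#' * branching single-node and multi-node ("hard") components have their
#'   candidate trajectories enumerated — via the embedded per-component
#'   dynamic program, already filtered for compatibility with the horizon
#'   constraint — and are fixed candidate-by-candidate with recursion and
#'   backtracking;
#' * hard components with condensation out-degree 0 (leaves) are checked
#'   sequentially, never recursively: nothing downstream depends on them, so
#'   each needs only one satisfying candidate of its own;
#' * weakly connected blocks of the condensation are searched independently,
#'   so the work over independent subnetworks adds instead of multiplying.
#'
#' A reported "solvable" is always backed by a concrete control sequence
#' extracted by backward regression over the fixed trajectories and verified
#' by forward simulation; extraction explores input-combination choices
#' exhaustively (restricted to gamma-admissible values), so per-node gamma
#' overcounting — possible only through self-loops on simple nodes — can
#' never produce a wrong decision.
#'
#' @param problem a [control_problem()].
#' @param find_sequence include the extracted control sequence in the result
#'   (extraction and verification happen regardless; this only controls the
#'   returned object).
#' @param max_states resource cap on the total number of candidate component
#'   trajectories fixed during the search (default 1e7); exceeding it raises
#'   a `bn_resource_error` rather than returning a wrong decision.
#' @param max_candidates cap on the candidate list of a single component.
#' @return An object of class `bn_control_result`: `solvable`, `controls`
#'   (tau x m matrix or NULL), `verified`, and `stats` (list with
#'   `states_enumerated`, `backtracks`, `components`,
#'   `multi_node_components`, `candidate_counts`).
#' @examples
#' res <- solve_control(fig6_problem())
#' res$solvable
#' res$controls
#' @export
solve_control <- function(problem, find_sequence = TRUE,
                          max_states = 1e7, max_candidates = 65536L) {
  stopifnot(inherits(problem, "control_problem"))
  net <- problem$network
  tau <- problem$tau
  n <- length(net$internal)
  m <- length(net$external)
  dec <- decompose_network(net)

  stats <- new.env(parent = emptyenv())
  stats$states_enumerated <- 0
  stats$backtracks <- 0
  stats$candidate_counts <- numeric(0)
  stat_list <- function() list(
    states_enumerated = stats$states_enumerated,
    backtracks = stats$backtracks,
    components = length(dec),
    multi_node_components = sum(vapply(dec, `[[`, "", "category") == "MULTI_NODE"),
    candidate_counts = stats$candidate_counts
  )
  result <- function(solvable, controls = NULL, verified = FALSE) {
    structure(list(solvable = solvable,
                   controls = if (find_sequence) controls else NULL,
                   verified = verified, stats = stat_list(), problem = problem),
              class = "bn_control_result")
  }

  cons <- which(!is.na(problem$desired))

  if (tau == 0L) {
    ok <- all(problem$initial[cons] == problem$desired[cons])
    ctr <- matrix(integer(), nrow = 0L, ncol = m,
                  dimnames = list(NULL, net$external))
    return(result(ok, controls = if (ok) ctr, verified = ok))
  }

  ## provably correct early rejection on (eventually) constant nodes
  fz <- frozen_nodes(net, problem$initial)
  for (r in seq_len(nrow(fz))) {
    v <- fz$node[r]
    if (!is.na(problem$desired[v]) && tau >= fz$from_t[r] &&
        problem$desired[v] != fz$value[r]) {
      return(result(FALSE))
    }
  }

  compiled <- compile_network(net)
  gamma0 <- new_gamma(net, problem$initial, tau)
  islands <- split(seq_along(dec), vapply(dec, `[[`, integer(1), "island"))
  islands <- islands[order(vapply(islands, min, integer(1)))]

  all_fixed <- list()
  for (isl in islands) {
    comps <- dec[isl]
    out <- search_island(comps, net, compiled, problem, gamma0, stats,
                         max_states, max_candidates)
    if (is.null(out)) return(result(FALSE))
    all_fixed <- c(all_fixed, out)
  }

  ## assemble the control matrix: fixed external trajectories, demanded
  ## bits, remaining free bits default to 0
  controls <- matrix(0L, nrow = tau, ncol = m,
                     dimnames = list(NULL, net$external))
  for (item in all_fixed) {
    e <- item$node
    if (!(e %in% net$external)) next
    controls[item$t + 1L, e] <- item$value
  }
  if (!verify_control(problem, controls)) {
    stop("internal inconsistency: extracted control sequence failed verification; ",
         "please report this as a solver bug", call. = FALSE)
  }
  result(TRUE, controls = controls, verified = TRUE)
}

#' @export
print.bn_control_result <- function(x, ...) {
  if (x$solvable) {
    cat(sprintf("Control problem solvable at tau = %d (sequence verified: %s)\n",
                x$problem$tau, if (isTRUE(x$verified)) "yes" else "no"))
    if (!is.null(x$switch_count)) {
      cat(sprintf("  control-node switches: %d (minimized)\n", x$switch_count))
    }
    if (!is.null(x$controls) && ncol(x$controls)) {
      tab <- x$controls
      rownames(tab) <- paste0("t", seq_len(nrow(tab)) - 1L)
      print(tab)
    }
  } else {
    cat(sprintf("No control sequence exists for tau = %d\n", x$problem$tau))
  }
  invisible(x)
}

#' @export
summary.bn_control_result <- function(object, ...) {
  print(object)
  s <- object$stats
  cat(sprintf("components: %d (%d multi-node); candidate trajectories fixed: %d; backtracks: %d\n",
              s$components, s$multi_node_components,
              s$states_enumerated, s$backtracks))
  if (length(s$candidate_counts)) {
    cat("candidate counts per hard component:\n")
    for (nm in names(s$candidate_counts)) {
      cat(sprintf("  {%s}: %d\n", nm, s$candidate_counts[[nm]]))
    }
  }
  invisible(object)
}

## ---- island search ---------------------------------------------------------

## Returns NULL on failure, else a list of assignments
## list(node=, t=, value=) for external control bits implied by the
## successful fixing + extraction of this island.
search_island <- function(comps, net, compiled, problem, gamma, stats,
                          max_states, max_candidates) {
  tau <- problem$tau
  is_leaf_hard <- vapply(comps, function(cc) {
    cc$category != "SIMPLE_NONBRANCHING" && cc$out_degree == 0L
  }, logical(1))
  seq_comps <- comps[!is_leaf_hard]
  leaf_comps <- comps[is_leaf_hard]

  rec <- function(i, gamma, fixed) {
    if (i > length(seq_comps)) {
      return(finish_island(comps, leaf_comps, net, compiled, problem, gamma,
                           fixed, stats, max_states, max_candidates))
    }
    comp <- seq_comps[[i]]
    if (comp$category == "SIMPLE_NONBRANCHING") {
      v <- comp$members
      if (v %in% net$external) return(rec(i + 1L, gamma, fixed))
      for (t in 0:(tau - 1L)) {
        g <- gamma_simple(v, net, gamma, t)
        gamma$g0[v, t + 2L] <- g[["g0"]]
        gamma$g1[v, t + 2L] <- g[["g1"]]
      }
      d <- problem$desired[v]
      if (!is.na(d)) {
        bit_ok <- if (d == 1L) gamma$g1[v, tau + 1L] else gamma$g0[v, tau + 1L]
        if (!bit_ok) return(NULL)  # early rejection at the horizon
      }
      return(rec(i + 1L, gamma, fixed))
    }
    ## hard, non-leaf: enumerate candidates, fix, recurse
    cands <- hard_candidates(comp, net, compiled, problem, gamma, max_candidates)
    label <- paste(comp$members, collapse = ",")
    if (is.na(stats$candidate_counts[label])) {
      stats$candidate_counts[label] <- length(cands)
    }
    for (cand in cands) {
      stats$states_enumerated <- stats$states_enumerated + 1
      if (stats$states_enumerated > max_states) {
        stop(bn_resource_error("search exceeded max_states candidate fixings"))
      }
      g2 <- gamma
      f2 <- fixed
      for (v in comp$members) {
        g2 <- set_gamma_fixed(g2, v, cand[v, ])
        f2[[v]] <- cand[v, ]
      }
      res <- rec(i + 1L, g2, f2)
      if (!is.null(res)) return(res)
      stats$backtracks <- stats$backtracks + 1
    }
    NULL
  }
  rec(1L, gamma, list())
}

## candidate trajectories for a hard component under the current gamma:
## paths of the per-component DP, pre-filtered for compatibility with the
## horizon restriction (no backtracking ever happens on t = tau)
hard_candidates <- function(comp, net, compiled, problem, gamma, max_candidates) {
  mem <- comp$members
  internal_mem <- intersect(mem, net$internal)
  init_r <- if (length(internal_mem)) problem$initial[internal_mem] else NULL
  dd <- problem$desired[internal_mem]
  dd <- dd[!is.na(dd)]
  reach <- component_reach(net, mem, problem$tau, init = init_r,
                           desired = if (length(dd)) dd else NULL,
                           allowed = function(node, t) gamma_allowed(gamma, node, t),
                           compiled = compiled)
  lapply(component_paths(reach, max_candidates),
         function(p) path_to_trajectory(reach, p))
}

## ---- extraction ------------------------------------------------------------

## After the sequential components are fixed: handle leaf hard components
## sequentially (each needs one satisfying, realizable candidate of its own),
## then realize every fixed trajectory and every horizon demand by backward
## regression.  The regression is organized in independent units: every
## simple node has at most one consumer, so demand cascades from different
## roots can never touch the same (node, time) slot, and each unit is a
## small complete backtracking search over input-value choices restricted to
## gamma-admissible bits.
finish_island <- function(comps, leaf_comps, net, compiled, problem, gamma,
                          fixed, stats, max_states, max_candidates) {
  tau <- problem$tau
  ctx <- new.env(parent = emptyenv())
  ctx$store <- new.env(parent = emptyenv())  # "node|t" -> bit (demands + controls)
  ctx$net <- net
  ctx$compiled <- compiled
  ctx$problem <- problem
  ctx$fixed <- fixed
  ctx$gamma <- gamma

  roots <- unit_roots(comps, net)

  ## leaf hard components: sequential candidate loop, each wrapped around its
  ## own realization unit
  for (comp in leaf_comps) {
    cands <- hard_candidates(comp, net, compiled, problem, gamma, max_candidates)
    label <- paste(comp$members, collapse = ",")
    if (is.na(stats$candidate_counts[label])) {
      stats$candidate_counts[label] <- length(cands)
    }
    done <- FALSE
    for (cand in cands) {
      stats$states_enumerated <- stats$states_enumerated + 1
      if (stats$states_enumerated > max_states) {
        stop(bn_resource_error("search exceeded max_states candidate fixings"))
      }
      for (v in comp$members) {
        ctx$gamma <- set_gamma_fixed(ctx$gamma, v, cand[v, ])
        ctx$fixed[[v]] <- cand[v, ]
      }
      tasks <- unit_tasks(comp, comps, roots, ctx)
      if (csp_solve(tasks, ctx)) { done <- TRUE; break }
      stats$backtracks <- stats$backtracks + 1
      for (v in comp$members) ctx$fixed[[v]] <- NULL
    }
    if (!done) return(NULL)
  }

  ## non-leaf hard components and terminal simple trees
  leaf_ids <- vapply(leaf_comps, function(cc) paste(cc$members, collapse = ","), "")
  for (comp in comps) {
    id <- paste(comp$members, collapse = ",")
    if (id %in% leaf_ids) next
    if (comp$category == "SIMPLE_NONBRANCHING" && !identical(roots[[comp$members]], comp$members)) {
      next  # realized within its root's unit
    }
    tasks <- unit_tasks(comp, comps, roots, ctx)
    if (!csp_solve(tasks, ctx)) return(NULL)
  }

  ## harvest external control bits from fixed trajectories and demands
  out <- list()
  for (e in intersect(names(ctx$fixed), net$external)) {
    for (t in 0:(tau - 1L)) {
      out[[length(out) + 1L]] <- list(node = e, t = t, value = ctx$fixed[[e]][t + 1L])
    }
  }
  for (key in ls(ctx$store)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    v <- parts[1]; t <- as.integer(parts[2])
    if (v %in% net$external && t <= tau - 1L) {
      out[[length(out) + 1L]] <- list(node = v, t = t, value = ctx$store[[key]])
    }
  }
  out
}

## root of the demand cascade for every simple unfixed node: follow the
## unique consumer chain until a hard component (or a dead end) is reached
unit_roots <- function(comps, net) {
  g <- dependency_graph(net)
  el <- igraph::as_edgelist(g, names = TRUE)
  comp_of <- list()
  for (comp in comps) for (v in comp$members) comp_of[[v]] <- comp
  roots <- list()
  find_root <- function(v) {
    if (!is.null(roots[[v]])) return(roots[[v]])
    comp <- comp_of[[v]]
    if (is.null(comp)) return(NULL)  # node from another island
    if (comp$category != "SIMPLE_NONBRANCHING") {
      return(paste(comp$members, collapse = ","))
    }
    outs <- setdiff(unique(el[el[, 1] == v, 2]), v)
    outs <- outs[outs %in% names(comp_of)]
    if (length(outs) == 0L) return(v)
    find_root(outs[[1L]])
  }
  for (comp in comps) for (v in comp$members) {
    r <- find_root(v)
    if (!is.null(r)) roots[[v]] <- r
  }
  roots
}

## tasks of the unit rooted at `comp`: realization of its fixed trajectory
## (hard components) plus the horizon demands of every simple node whose
## cascade ends at this root
unit_tasks <- function(comp, comps, roots, ctx) {
  tau <- ctx$problem$tau
  root_id <- if (comp$category == "SIMPLE_NONBRANCHING") comp$members
             else paste(comp$members, collapse = ",")
  tasks <- list()
  if (comp$category != "SIMPLE_NONBRANCHING") {
    for (t in tau:1L) {
      tasks[[length(tasks) + 1L]] <- list(type = "realize", comp = comp, t = t)
    }
  }
  for (other in comps) {
    if (other$category != "SIMPLE_NONBRANCHING") next
    v <- other$members
    if (!identical(roots[[v]], root_id)) next
    if (v %in% ctx$net$external) next
    d <- ctx$problem$desired[v]
    if (!is.na(d)) {
      tasks[[length(tasks) + 1L]] <- list(type = "demand", node = v, t = tau,
                                          value = as.integer(d))
    }
  }
  tasks
}

## ---- the regression CSP ---------------------------------------------------

store_key <- function(v, t) paste(v, t, sep = "|")

## admissible values for node `w` at time `t` given fixings, demands and gamma
csp_values <- function(w, t, ctx) {
  if (!is.null(ctx$fixed[[w]])) return(ctx$fixed[[w]][t + 1L])
  key <- store_key(w, t)
  if (!is.null(ctx$store[[key]])) return(ctx$store[[key]])
  if (w %in% ctx$net$internal && t == 0L) return(ctx$problem$initial[[w]])
  gamma_allowed(ctx$gamma, w, t)
}

## solve the task list by depth-first search; tasks are consumed in order of
## decreasing time step so every choice only ever posts demands at earlier
## steps.  Returns TRUE and leaves the successful demands in ctx$store.
csp_solve <- function(tasks, ctx) {
  if (length(tasks) == 0L) return(TRUE)
  ts <- vapply(tasks, `[[`, integer(1), "t")
  i <- which.max(ts)
  task <- tasks[[i]]
  rest <- tasks[-i]

  if (task$type == "demand") {
    v <- task$node; t <- task$t; b <- task$value
    ## fixed / already-demanded / initial slots: consistency check only
    if (!is.null(ctx$fixed[[v]])) {
      return(if (ctx$fixed[[v]][t + 1L] == b) csp_solve(rest, ctx) else FALSE)
    }
    key <- store_key(v, t)
    if (!is.null(ctx$store[[key]])) {
      return(if (ctx$store[[key]] == b) csp_solve(rest, ctx) else FALSE)
    }
    if (v %in% ctx$net$external) {
      ctx$store[[key]] <- b
      if (csp_solve(rest, ctx)) return(TRUE)
      rm(list = key, envir = ctx$store)
      return(FALSE)
    }
    if (t == 0L) return(ctx$problem$initial[[v]] == b)
    if (!(b %in% gamma_allowed(ctx$gamma, v, t))) return(FALSE)
    ctx$store[[key]] <- b
    f <- ctx$net$functions[[v]]
    vars <- expression_vars(f)
    ok <- try_combos(vars, t - 1L, ctx, function(asn) {
      evaluate_expression(f, asn) == b
    }, rest)
    if (!ok) rm(list = key, envir = ctx$store)
    return(ok)
  }

  if (task$type == "realize") {
    comp <- task$comp; t <- task$t
    mem <- comp$members
    internal_mem <- intersect(mem, ctx$net$internal)
    ups <- setdiff(unique(unlist(lapply(internal_mem, function(v) {
      expression_vars(ctx$net$functions[[v]])
    }))), mem)
    prev <- vapply(mem, function(v) ctx$fixed[[v]][t], integer(1))
    target <- vapply(internal_mem, function(v) ctx$fixed[[v]][t + 1L], integer(1))
    ok <- try_combos(ups, t - 1L, ctx, function(asn) {
      full <- c(prev, asn)
      all(vapply(internal_mem, function(v) {
        evaluate_expression(ctx$net$functions[[v]], full)
      }, integer(1)) == target)
    }, rest)
    return(ok)
  }
  stop("unknown extraction task type")
}

## enumerate assignments of `vars` at time `t` over their admissible values;
## for each assignment passing `pred`, post the implied demands and recurse
try_combos <- function(vars, t, ctx, pred, rest) {
  sets <- lapply(vars, function(w) csp_values(w, t, ctx))
  if (any(lengths(sets) == 0L)) return(FALSE)
  grid <- if (length(vars)) {
    do.call(expand.grid, c(stats::setNames(sets, vars), KEEP.OUT.ATTRS = FALSE))
  } else data.frame(row.names = 1L)
  for (r in seq_len(max(nrow(grid), 1L))) {
    asn <- if (length(vars)) stats::setNames(as.integer(grid[r, ]), vars) else
      stats::setNames(integer(0), character(0))
    if (!pred(asn)) next
    ## post demands for slots not yet pinned down
    new_tasks <- rest
    added <- character(0)
    feasible <- TRUE
    for (w in vars) {
      if (!is.null(ctx$fixed[[w]])) next
      key <- store_key(w, t)
      if (!is.null(ctx$store[[key]])) next
      if (w %in% ctx$net$internal && t == 0L) next  # checked via csp_values
      if (w %in% ctx$net$external) {
        ctx$store[[key]] <- asn[[w]]
        added <- c(added, key)
      } else {
        new_tasks[[length(new_tasks) + 1L]] <- list(type = "demand", node = w,
                                                    t = t, value = asn[[w]])
      }
    }
    if (feasible && csp_solve(new_tasks, ctx)) return(TRUE)
    if (length(added)) rm(list = added, envir = ctx$store)
  }
  FALSE
}

## ---- candidate enumeration (exported view) --------------------------------

#' Enumerate the candidate trajectories of a component
#'
#' Lists the per-time state sequences a component can follow over t = 0..tau,
#' given the reachability context of everything upstream (a gamma table; by
#' default computed fresh with [compute_gamma()]). For an unconstrained
#' single external node this is all 2^(tau+1) bit sequences, ordered by
#' binary counting with t = 0 as the least significant digit (the all-zero
#' sequence first, then the sequence with a single 1 at t = 0, ...); for
#' components with dynamics only sequences consistent with the update
#' functions and the upstream context are returned, in the same documented
#' key order. An empty list is a valid result and signals that the component
#' forces a backtrack.
#'
#' @param network a [boolean_network()].
#' @param members character vector: the component's members.
#' @param tau horizon.
#' @param initial named bit vector over the network's internal nodes.
#' @param desired optional horizon restriction (named bits, NA = don't care);
#'   candidates incompatible with it are filtered out.
#' @param gamma optional `gamma_table` supplying the upstream context;
#'   computed with [compute_gamma()] when omitted.
#' @param max_candidates enumeration cap.
#' @return List of members x (tau + 1) bit matrices.
#' @examples
#' cands <- enumerate_component_sequences(fig6_network(), "u", tau = 3,
#'                                        initial = fig6_initial())
#' length(cands)       # 16
#' cands[[2]]["u", ]   # 1 0 0 0
#' @export
enumerate_component_sequences <- function(network, members, tau, initial,
                                          desired = NULL, gamma = NULL,
                                          max_candidates = 65536L) {
  if (is.null(gamma)) gamma <- compute_gamma(network, initial, tau)
  initial <- check_state(initial, network$internal, "initial state")
  internal_mem <- intersect(members, network$internal)
  init_r <- if (length(internal_mem)) initial[internal_mem] else NULL
  dd <- NULL
  if (!is.null(desired)) {
    desired <- check_state(desired, network$internal, "desired state",
                           allow_na = TRUE)
    dd <- desired[internal_mem]
    dd <- dd[!is.na(dd)]
    if (!length(dd)) dd <- NULL
  }
  reach <- component_reach(network, members, as.integer(tau), init = init_r,
                           desired = dd,
                           allowed = function(node, t) gamma_allowed(gamma, node, t))
  lapply(component_paths(reach, max_candidates),
         function(p) path_to_trajectory(reach, p))
}
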