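`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dependency graph of a Boolean network
#'
#' Builds the directed wiring diagram: an edge j -> i is present exactly when
#' node j's name occurs as a variable in the update function of internal node
#' i (logically vacuous occurrences still count; self-loops allowed).
#' External nodes have in-degree 0 by construction.
#'
#' @param network a [boolean_network()].
#' @return An [igraph::graph] with one vertex per node (internal then
#'   external, declaration order).
#' @export
dependency_graph <- function(network) {
  all_names <- c(network$internal, network$external)
  edges <- character()
  for (v in network$internal) {
    for (src in expression_vars(network$functions[[v]])) {
      edges <- c(edges, src, v)
    }
  }
  igraph::graph_from_data_frame(
    d = if (length(edges)) {
      em <- matrix(edges, ncol = 2, byrow = TRUE)
      data.frame(from = em[, 1], to = em[, 2])
    } else data.frame(from = character(), to = character()),
    directed = TRUE,
    vertices = data.frame(name = all_names)
  )
}

#' Decompose a network into strongly connected components
#'
#' Partitions the dependency graph into strongly connected components (SCCs),
#' orders them topologically along the condensation, and classifies each one:
#'
#' * `MULTI_NODE` — two or more members (a feedback structure);
#' * `BRANCHING_SINGLE` — a single node with at least two distinct dependency
#'   successors outside itself (its downstream consumers can impose mutually
#'   dependent constraints);
#' * `SIMPLE_NONBRANCHING` — a single node with at most one outside successor.
#'
#' A self-loop does not make a singleton component multi-node and does not
#' count as an outgoing edge for the branching test. Among valid topological
#' orders the deterministic one is chosen: ties are broken by the smallest
#' declared-node index of the members.
#'
#' @param network a [boolean_network()].
#' @return An object of class `bn_decomposition`: a list of components, each
#'   with `members`, `topo_index`, `category`, `out_degree` (condensation
#'   out-degree) and `island` (weakly connected block of the condensation).
#' @examples
#' decompose_network(fig6_network())
#' @export
decompose_network <- function(network) {
  g <- dependency_graph(network)
  all_names <- c(network$internal, network$external)
  comp <- igraph::components(g, mode = "strong")
  membership <- comp$membership[all_names]
  k <- comp$no

  members <- split(all_names, membership)

  ## condensation adjacency (distinct component successors, no self edges)
  succ <- vector("list", k)
  pred_count <- integer(k)
  el <- igraph::as_edgelist(g, names = TRUE)
  for (r in seq_len(nrow(el))) {
    a <- membership[[el[r, 1]]]
    b <- membership[[el[r, 2]]]
    if (a != b && !(b %in% succ[[a]])) {
      succ[[a]] <- c(succ[[a]], b)
      pred_count[b] <- pred_count[b] + 1L
    }
  }

  ## Kahn's algorithm with smallest-member-index priority for a stable order
  min_member <- vapply(members, function(mm) min(match(mm, all_names)), integer(1))
  ready <- which(pred_count == 0L)
  order_ids <- integer(0)
  remaining <- pred_count
  while (length(ready)) {
    nxt <- ready[which.min(min_member[ready])]
    ready <- setdiff(ready, nxt)
    order_ids <- c(order_ids, nxt)
    for (b in succ[[nxt]]) {
      remaining[b] <- remaining[b] - 1L
      if (remaining[b] == 0L) ready <- c(ready, b)
    }
  }
  stopifnot(length(order_ids) == k)

  ## weakly connected blocks of the condensation ("islands"): independent
  ## subproblems whose searches never interact
  cond_edges <- data.frame(
    from = as.character(rep(seq_len(k), lengths(succ))),
    to = as.character(unlist(succ, use.names = FALSE) %||% integer(0))
  )
  cond <- igraph::graph_from_data_frame(
    d = cond_edges, directed = TRUE,
    vertices = data.frame(name = as.character(seq_len(k)))
  )
  weak <- igraph::components(cond, mode = "weak")$membership

  out_deg <- lengths(succ)
  comps <- lapply(seq_along(order_ids), function(pos) {
    id <- order_ids[pos]
    mm <- members[[id]]
    mm <- mm[order(match(mm, all_names))]
    category <- if (length(mm) >= 2L) {
      "MULTI_NODE"
    } else {
      node <- mm
      outs <- setdiff(unique(el[el[, 1] == node, 2]), node)
      if (length(outs) >= 2L) "BRANCHING_SINGLE" else "SIMPLE_NONBRANCHING"
    }
    list(members = mm, topo_index = pos, category = category,
         out_degree = as.integer(out_deg[[id]]),
         island = as.integer(weak[[as.character(id)]]))
  })
  structure(comps, class = "bn_decomposition",
            network_nodes = all_names)
}

#' @export
print.bn_decomposition <- function(x, ...) {
  cat(sprintf("%d strongly connected component(s) in topological order:\n", length(x)))
  for (cc in x) {
    cat(sprintf("  #%d [%s] {%s}  (condensation out-degree %d, island %d)\n",
                cc$topo_index, cc$category, paste(cc$members, collapse = ", "),
                cc$out_degree, cc$island))
  }
  invisible(x)
}

#' @export
as.data.frame.bn_decomposition <- function(x, ...) {
  data.frame(
    topo_index = vapply(x, `[[`, integer(1), "topo_index"),
    members = vapply(x, function(cc) paste(cc$members, collapse = ","), ""),
    size = vapply(x, function(cc) length(cc$members), integer(1)),
    category = vapply(x, `[[`, "", "category"),
    out_degree = vapply(x, `[[`, integer(1), "out_degree"),
    island = vapply(x, `[[`, integer(1), "island")
  )
}

#' Provably constant ("frozen") and eventually-constant nodes
#'
#' Finds internal nodes whose value is independent of every control choice:
#' constant functions, nodes with no inputs, pure self-copies (pinned to
#' their initial value), and — by fixpoint iteration — any node whose update
#' function becomes constant once its constant inputs are substituted
#' (e.g. `en <- !SLP` with `SLP` frozen). Each such node is reported with the
#' first time step `from_t` at which its value is guaranteed: `from_t = 0`
#' means frozen at all times, `from_t = k > 0` means eventually constant from
#' step k onward.
#'
#' The solver uses this table for provably correct early rejection: a desired
#' value that contradicts a constant node at the horizon can be refused
#' before any search.
#'
#' @param network a [boolean_network()].
#' @param initial named bit vector over internal nodes at t = 0.
#' @return A data.frame with columns `node`, `value`, `from_t`.
#' @examples
#' fx <- drosophila_problem()
#' frozen_nodes(fx$network, fx$initial)
#' @export
frozen_nodes <- function(network, initial) {
  initial <- check_state(initial, network$internal, "initial state")
  const_val <- c()   # node -> constant value
  const_from <- c()  # node -> first guaranteed time step

  ## base: pure self-copies are pinned to their initial value for all t
  for (v in network$internal) {
    f <- network$functions[[v]]
    if (f$op == "var" && f$name == v) {
      const_val[v] <- initial[[v]]
      const_from[v] <- 0L
    }
  }

  repeat {
    changed <- FALSE
    for (v in setdiff(network$internal, names(const_val))) {
      vars <- expression_vars(network$functions[[v]])
      known <- intersect(vars, names(const_val))
      free <- setdiff(vars, known)
      if (v %in% free) next  # non-trivial self-dependence: not provably constant
      ## constant over every assignment of the free inputs?
      kf <- length(free)
      vals <- integer(0)
      for (r in seq_len(bitwShiftL(1L, kf)) - 1L) {
        asn <- c(const_val[known],
                 stats::setNames(bitwAnd(bitwShiftR(r, seq_len(kf) - 1L), 1L), free))
        vals <- c(vals, evaluate_expression(network$functions[[v]], asn))
        if (length(unique(vals)) > 1L) break
      }
      if (length(unique(vals)) == 1L) {
        from <- if (length(known)) max(const_from[known]) + 1L else 1L
        if (from == 1L && initial[[v]] == vals[1L]) from <- 0L
        const_val[v] <- vals[1L]
        const_from[v] <- from
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  nodes <- intersect(network$internal, names(const_val))
  data.frame(node = nodes,
             value = unname(const_val[nodes]),
             from_t = unname(const_from[nodes]))
}
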