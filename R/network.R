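#' Construct a synchronous Boolean network
#'
#' A Boolean network is a set of internal nodes, each with exactly one update
#' function over AND/OR/NOT, plus a (possibly empty) set of external control
#' nodes. External nodes have no update function and no incoming edges; their
#' values are chosen freely at every time step. All nodes update synchronously:
#' the state at time t+1 is computed entirely from values at time t.
#'
#' @param functions named list of update rules for the internal nodes, in
#'   declaration order. Each element is either a formula string (parsed with
#'   [parse_boolean_expression()]) or a `boolean_expression`.
#' @param external character vector of external (control) node names.
#' @return An object of class `boolean_network` with fields `internal`,
#'   `external` and `functions` (one AST per internal node).
#' @examples
#' net <- boolean_network(list(a = "u", b = "a & !u"), external = "u")
#' net
#' @export
boolean_network <- function(functions, external = character()) {
  if (length(functions) == 0L && length(external) == 0L) {
    stop("network must declare at least one node", call. = FALSE)
  }
  if (length(functions) > 0L && is.null(names(functions))) {
    stop("update functions must be a named list (target node names)", call. = FALSE)
  }
  internal <- names(functions)
  external <- as.character(external)
  all_names <- c(internal, external)
  if (anyDuplicated(all_names)) {
    stop("duplicate node name(s): ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- all_names[!grepl("^[A-Za-z][A-Za-z0-9_-]*$", all_names)]
  if (length(bad)) {
    stop("invalid node name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  asts <- lapply(functions, function(f) {
    if (inherits(f, "boolean_expression")) f else parse_boolean_expression(f)
  })
  ## every referenced variable must be a declared node
  for (target in internal) {
    vars <- expression_vars(asts[[target]])
    missing <- setdiff(vars, all_names)
    if (length(missing)) {
      stop(sprintf("update function of '%s' references undeclared node(s): %s",
                   target, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  structure(
    list(internal = internal, external = external, functions = asts),
    class = "boolean_network"
  )
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Synchronous Boolean network: %d internal node(s), %d external node(s)\n",
              length(x$internal), length(x$external)))
  if (length(x$external)) {
    cat("  external:", paste(x$external, collapse = ", "), "\n")
  }
  for (v in x$internal) {
    cat(sprintf("  %s <- %s\n", v, render_expression(x$functions[[v]])))
  }
  invisible(x)
}

#' @export
summary.boolean_network <- function(object, ...) {
  dec <- decompose_network(object)
  cat(sprintf("Boolean network: n = %d internal, m = %d external, %d dependency edge(s)\n",
              length(object$internal), length(object$external),
              igraph::ecount(dependency_graph(object))))
  print(dec)
  invisible(object)
}

## ---- compiled form ---------------------------------------------------------

## Per internal node: the distinct input nodes (declaration order), their
## indices in the combined (internal, external) ordering, and the function's
## truth table indexed by sum(bit_j * 2^(j-1)) over the inputs.  All state
## vectors are also carried as integer encodings (first declared node = least
## significant bit), which makes stepping a vectorized table lookup.
compile_network <- function(net) {
  n <- length(net$internal)
  m <- length(net$external)
  all_names <- c(net$internal, net$external)
  nodes <- lapply(net$internal, function(v) {
    vars <- expression_vars(net$functions[[v]])
    idx <- match(vars, all_names)
    ord <- order(idx)
    vars <- vars[ord]
    idx <- idx[ord]
    list(inputs = vars, idx = idx,
         tt = expression_truth_table(net$functions[[v]], vars))
  })
  names(nodes) <- net$internal
  list(n = n, m = m, names = all_names, nodes = nodes)
}

encode_bits <- function(values, nodes) {
  v <- as.integer(values[nodes])
  if (anyNA(v)) stop("state does not assign: ",
                     paste(nodes[is.na(v)], collapse = ", "), call. = FALSE)
  if (!all(v %in% c(0L, 1L))) stop("state values must be 0/1 bits", call. = FALSE)
  sum(v * 2^(seq_along(nodes) - 1L))
}

decode_bits <- function(code, nodes) {
  bits <- code %/% 2^(seq_along(nodes) - 1L) %% 2
  stats::setNames(as.integer(bits), nodes)
}

## Vectorized synchronous step on encoded states.  S: encoded internal
## states; U: encoded external assignments (recycled if scalar).  Uses
## numeric arithmetic (exact for < 2^53) so n + m is not limited to 31 bits
## by R's integer type; practical sizes are far smaller.
step_encoded <- function(compiled, S, U = 0) {
  n <- compiled$n
  S <- as.numeric(S); U <- as.numeric(U)
  out <- numeric(max(length(S), length(U)))
  for (j in seq_len(n)) {
    node <- compiled$nodes[[j]]
    idx <- 0
    for (p in seq_along(node$idx)) {
      ci <- node$idx[p]
      bit <- if (ci <= n) (S %/% 2^(ci - 1L)) %% 2 else (U %/% 2^(ci - n - 1L)) %% 2
      idx <- idx + bit * 2^(p - 1L)
    }
    out <- out + node$tt[idx + 1] * 2^(j - 1L)
  }
  out
}

## ---- states, problems, trajectories ---------------------------------------

check_state <- function(values, nodes, what = "state", allow_na = FALSE) {
  if (length(nodes) == 0L) return(stats::setNames(integer(0), character(0)))
  values <- unlist(values)
  if (is.null(names(values))) stop(what, " must be a named vector", call. = FALSE)
  missing <- setdiff(nodes, names(values))
  if (length(missing)) {
    stop(what, " does not assign node(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(values), nodes)
  if (length(extra)) {
    stop(what, " assigns undeclared node(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  v <- suppressWarnings(as.integer(values[nodes]))
  ok <- v %in% c(0L, 1L) | (allow_na & is.na(v))
  if (!all(ok)) stop(what, " values must be 0/1 bits", call. = FALSE)
  stats::setNames(v, nodes)
}

#' Define a finite-horizon control problem
#'
#' @param network a [boolean_network()].
#' @param initial named bit vector: the state of every internal node at t = 0.
#' @param desired named bit vector: the required state of internal nodes at
#'   t = tau. Entries may be `NA` ("don't care"), leaving that node
#'   unconstrained at the horizon.
#' @param tau control horizon, a non-negative integer number of synchronous
#'   update steps.
#' @return An object of class `control_problem`.
#' @export
control_problem <- function(network, initial, desired, tau) {
  stopifnot(inherits(network, "boolean_network"))
  tau <- as.integer(tau)
  if (length(tau) != 1L || is.na(tau) || tau < 0L) {
    stop("tau must be a single non-negative integer", call. = FALSE)
  }
  initial <- check_state(initial, network$internal, "initial state")
  desired <- check_state(desired, network$internal, "desired state", allow_na = TRUE)
  structure(list(network = network, initial = initial, desired = desired, tau = tau),
            class = "control_problem")
}

#' @export
print.control_problem <- function(x, ...) {
  net <- x$network
  cat(sprintf("Boolean network control problem: n = %d, m = %d, tau = %d\n",
              length(net$internal), length(net$external), x$tau))
  cons <- !is.na(x$desired)
  cat(sprintf("  initial: %s\n", paste0(net$internal, "=", x$initial, collapse = " ")))
  cat(sprintf("  desired: %s\n",
              paste0(net$internal[cons], "=", x$desired[cons], collapse = " ")))
  if (any(!cons)) cat("  don't-care:", paste(net$internal[!cons], collapse = " "), "\n")
  invisible(x)
}

## Normalize a control sequence to a tau x m integer matrix with external
## node names as columns, rows t = 0..tau-1.  Accepts a matrix/data.frame
## (tau rows) or a list of per-step named vectors.  A trailing row for t =
## tau is accepted and dropped with a warning: the assignment at the horizon
## cannot influence the state at the horizon.
as_control_matrix <- function(controls, network, tau) {
  m <- length(network$external)
  if (is.null(controls)) controls <- matrix(integer(), nrow = 0, ncol = m)
  if (is.list(controls) && !is.data.frame(controls)) {
    controls <- do.call(rbind, lapply(controls, function(row) {
      check_state(row, network$external, "control assignment")
    }))
    if (is.null(controls)) controls <- matrix(integer(), nrow = 0, ncol = m,
                                              dimnames = list(NULL, network$external))
  }
  controls <- as.matrix(controls)
  if (m > 0L && ncol(controls) != m) {
    stop(sprintf("control sequence must have %d column(s) (external nodes)", m),
         call. = FALSE)
  }
  if (m == 0L) controls <- matrix(integer(), nrow = tau, ncol = 0L)
  if (nrow(controls) == tau + 1L && tau >= 0L) {
    warning("control sequence has tau + 1 entries; ignoring the final assignment ",
            "(values at t = tau cannot influence the state at t = tau)")
    controls <- controls[seq_len(tau), , drop = FALSE]
  }
  if (nrow(controls) != tau) {
    stop(sprintf("control sequence must have tau = %d row(s), got %d", tau,
                 nrow(controls)), call. = FALSE)
  }
  if (m > 0L) {
    if (is.null(colnames(controls))) {
      colnames(controls) <- network$external
    } else {
      if (!setequal(colnames(controls), network$external)) {
        stop("control sequence columns must be the external nodes", call. = FALSE)
      }
      controls <- controls[, network$external, drop = FALSE]
    }
    storage.mode(controls) <- "integer"
    if (length(controls) && !all(controls %in% c(0L, 1L))) {
      stop("control values must be 0/1 bits", call. = FALSE)
    }
  }
  controls
}

#' Advance a network by one synchronous step
#'
#' Every internal node simultaneously takes the value of its update function
#' evaluated on the time-t values of its inputs.
#'
#' @param network a [boolean_network()].
#' @param state named bit vector over the internal nodes (time t).
#' @param external named bit vector over the external nodes (their values at
#'   time t); may be omitted when the network has no external nodes.
#' @return Named bit vector over the internal nodes at time t + 1.
#' @export
network_step <- function(network, state, external = c()) {
  state <- check_state(state, network$internal, "internal state")
  external <- check_state(external, network$external, "external assignment")
  assignment <- c(state, external)
  out <- vapply(network$internal, function(v) {
    evaluate_expression(network$functions[[v]], assignment)
  }, integer(1))
  stats::setNames(out, network$internal)
}

#' Simulate a controlled trajectory
#'
#' Iterates [network_step()] for `tau` steps under the given control
#' sequence.
#'
#' @param network a [boolean_network()].
#' @param initial named bit vector over internal nodes (t = 0).
#' @param controls control sequence: a `tau` x m matrix (columns = external
#'   nodes, row t+1 = assignment applied at time t), or a list of per-step
#'   named vectors. With no external nodes, `tau` must be given.
#' @param tau horizon; defaults to the number of control rows.
#' @return A (tau + 1) x n integer matrix of internal states, row labels
#'   `t0 ... ttau`.
#' @examples
#' net <- fig6_network()
#' bn_simulate(net, fig6_initial(), list(c(u = 1), c(u = 0), c(u = 0), c(u = 0)))
#' @export
bn_simulate <- function(network, initial, controls, tau = NULL) {
  initial <- check_state(initial, network$internal, "initial state")
  if (is.null(tau)) {
    tau <- if (is.matrix(controls) || is.data.frame(controls)) nrow(controls)
           else length(controls)
  }
  controls <- as_control_matrix(controls, network, tau)
  compiled <- compile_network(network)
  n <- length(network$internal)
  traj <- matrix(NA_integer_, nrow = tau + 1L, ncol = n,
                 dimnames = list(paste0("t", 0:tau), network$internal))
  s <- encode_bits(initial, network$internal)
  traj[1L, ] <- decode_bits(s, network$internal)
  for (t in seq_len(tau)) {
    u <- if (ncol(controls)) encode_bits(controls[t, ], network$external) else 0
    s <- step_encoded(compiled, s, u)
    traj[t + 1L, ] <- decode_bits(s, network$internal)
  }
  traj
}

#' Verify a control sequence against a problem
#'
#' Simulates the network forward under `controls` and checks that every
#' constrained internal node holds its desired value at t = tau.
#'
#' @param problem a [control_problem()].
#' @param controls a control sequence with exactly `tau` per-step assignments
#'   (see [bn_simulate()]).
#' @return `TRUE` if the sequence steers the network into the desired state.
#' @export
verify_control <- function(problem, controls) {
  stopifnot(inherits(problem, "control_problem"))
  traj <- bn_simulate(problem$network, problem$initial, controls, tau = problem$tau)
  final <- traj[problem$tau + 1L, ]
  cons <- !is.na(problem$desired)
  all(final[cons] == problem$desired[cons])
}
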