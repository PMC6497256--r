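## Independent oracles and instance builders used across the suite.

## mutual-reachability SCC partition via transitive closure (Floyd-Warshall
## style); adj[i, j] TRUE means an edge i -> j
closure_scc_partition <- function(adj) {
  n <- nrow(adj)
  R <- adj | diag(TRUE, n)
  for (k in seq_len(n)) {
    R <- R | outer(R[, k], R[k, ], "&")
  }
  mutual <- R & t(R)
  ## canonical label: smallest mutually-reachable index
  vapply(seq_len(n), function(i) min(which(mutual[i, ])), integer(1))
}

## random expression tree over the given variables
random_ast <- function(vars, depth = 4L) {
  if (depth == 0L || stats::runif(1) < 0.3) {
    if (stats::runif(1) < 0.15) {
      bexpr_const(sample(0:1, 1))
    } else {
      bexpr_var(sample(vars, 1))
    }
  } else {
    op <- sample(c("and", "or", "not"), 1)
    if (op == "not") {
      bexpr_not(random_ast(vars, depth - 1L))
    } else {
      k <- sample(2:3, 1)
      args <- lapply(seq_len(k), function(i) random_ast(vars, depth - 1L))
      do.call(if (op == "and") bexpr_and else bexpr_or, args)
    }
  }
}

## independent expression evaluation: hand the rendered formula to R's own
## parser (the dialect's tokens are valid R syntax for simple variable names)
eval_via_r <- function(text, assignment) {
  env <- list2env(as.list(stats::setNames(as.logical(assignment),
                                          names(assignment))),
                  parent = baseenv())
  as.integer(eval(parse(text = text), env))
}

## full truth table of an expression over explicit variables, via the
## package evaluator
truth_table_of <- function(expr, vars) {
  k <- length(vars)
  vapply(seq_len(2^k) - 1L, function(r) {
    bits <- bitwAnd(bitwShiftR(r, seq_len(k) - 1L), 1L)
    names(bits) <- vars
    evaluate_expression(expr, bits)
  }, integer(1))
}

## network realizing a given adjacency structure: node i's function is the
## OR of its inputs (every edge is a genuine dependency)
network_from_adjacency <- function(adj) {
  n <- nrow(adj)
  nodes <- paste0("n", seq_len(n))
  funs <- lapply(seq_len(n), function(i) {
    ins <- nodes[which(adj[, i])]
    if (length(ins) == 0L) return(bexpr_const(0L))
    if (length(ins) == 1L) return(bexpr_var(ins))
    do.call(bexpr_or, lapply(ins, bexpr_var))
  })
  names(funs) <- nodes
  boolean_network(funs)
}

## enumerate every control sequence explicitly (list of tau x m matrices),
## independent of the vectorized brute-force implementation
all_control_sequences <- function(network, tau) {
  m <- length(network$external)
  ks <- seq_len(2^(m * tau)) - 1L
  lapply(ks, function(k) {
    ctr <- matrix(0L, nrow = tau, ncol = m,
                  dimnames = list(NULL, network$external))
    if (tau > 0L && m > 0L) {
      for (t in 0:(tau - 1L)) {
        bits <- bitwAnd(bitwShiftR(k %/% 2^(m * t), seq_len(m) - 1L), 1L)
        ctr[t + 1L, ] <- bits
      }
    }
    ctr
  })
}

## the k-chain family used for the work-saving property: each unit has an
## external Ui feeding both ai and bi (making Ui a branching hard component)
## and a tail ci copying bi; units are pairwise independent
chain_network <- function(k) {
  funs <- list()
  ext <- character()
  for (i in seq_len(k)) {
    ui <- paste0("U", i); ai <- paste0("a", i)
    bi <- paste0("b", i); ci <- paste0("c", i)
    funs[[ai]] <- ui
    funs[[bi]] <- paste0(ui, " & ", ai)
    funs[[ci]] <- bi
    ext <- c(ext, ui)
  }
  boolean_network(funs, external = ext)
}

chain_problem <- function(k, tau = 3L) {
  net <- chain_network(k)
  init <- stats::setNames(rep(0L, 3L * k), net$internal)
  ctr <- matrix(1L, tau, k, dimnames = list(NULL, net$external))
  desired <- bn_simulate(net, init, ctr)[tau + 1L, ]
  control_problem(net, init, desired, tau)
}
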