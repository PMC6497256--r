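#' Read a Boolean network from a targets/factors file
#'
#' The network file is plain text: `#` starts a comment, an
#' `external: a, b, c` directive declares the control nodes, an optional
#' `targets, factors` header line is skipped, and every other non-blank
#' line reads `target, formula` with the formula in the
#' [parse_boolean_expression()] dialect. Round-trip stable: writing and
#' re-reading a network preserves every node's truth table.
#'
#' @param path file path.
#' @return A [boolean_network()].
#' @export
read_boolean_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  external <- character()
  funs <- list()
  seen_external_directive <- FALSE
  for (ln in seq_along(lines)) {
    line <- sub("#.*$", "", lines[ln])
    line <- trimws(line)
    if (line == "") next
    if (grepl("^external\\s*:", line, ignore.case = TRUE)) {
      decl <- sub("^external\\s*:", "", line, ignore.case = TRUE)
      external <- c(external, trimws(strsplit(decl, ",")[[1]]))
      external <- external[external != ""]
      seen_external_directive <- TRUE
      next
    }
    if (grepl("^targets\\s*,\\s*factors\\s*$", line, ignore.case = TRUE)) next
    comma <- regexpr(",", line, fixed = TRUE)
    if (comma < 0L) {
      stop(sprintf("line %d: expected 'target, formula'", ln), call. = FALSE)
    }
    target <- trimws(substr(line, 1L, comma - 1L))
    formula <- trimws(substr(line, comma + 1L, nchar(line)))
    if (target == "" || formula == "") {
      stop(sprintf("line %d: expected 'target, formula'", ln), call. = FALSE)
    }
    if (target %in% names(funs)) {
      stop(sprintf("line %d: duplicate target '%s'", ln, target), call. = FALSE)
    }
    funs[[target]] <- tryCatch(parse_boolean_expression(formula), error = function(e) {
      stop(sprintf("line %d: %s", ln, conditionMessage(e)), call. = FALSE)
    })
  }
  if (length(funs) == 0L) {
    stop("network file declares no internal nodes", call. = FALSE)
  }
  boolean_network(funs, external = external)
}

#' Write a Boolean network to a targets/factors file
#'
#' @param network a [boolean_network()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_boolean_network <- function(network, path) {
  lines <- character()
  if (length(network$external)) {
    lines <- c(lines, paste("external:", paste(network$external, collapse = ", ")))
  }
  lines <- c(lines, "targets, factors")
  for (v in network$internal) {
    lines <- c(lines, paste0(v, ", ", render_expression(network$functions[[v]])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a control problem from a YAML file
#'
#' Keys: `tau` (integer), `initial` (node -> bit map over the internal
#' nodes), `desired` (node -> bit, with `"-"` marking don't-care nodes),
#' and optionally `externals` (validated against the network's declaration).
#'
#' @param path file path.
#' @param network the [boolean_network()] the problem refers to.
#' @return A [control_problem()].
#' @export
read_control_problem <- function(path, network) {
  if (!file.exists(path)) stop("problem file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  for (key in c("tau", "initial", "desired")) {
    if (is.null(doc[[key]])) stop("problem file missing key: ", key, call. = FALSE)
  }
  if (!is.null(doc$externals) &&
      !setequal(as.character(doc$externals), network$external)) {
    stop("problem file external nodes do not match the network", call. = FALSE)
  }
  to_bits <- function(x, allow_dash = FALSE) {
    vals <- vapply(x, function(b) {
      if (allow_dash && (is.na(b) || identical(b, "-"))) return(NA_integer_)
      as.integer(b)
    }, integer(1))
    vals
  }
  control_problem(network,
                  initial = to_bits(doc$initial),
                  desired = to_bits(doc$desired, allow_dash = TRUE),
                  tau = doc$tau)
}

#' Write a control problem to a YAML file
#'
#' @param problem a [control_problem()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_control_problem <- function(problem, path) {
  net <- problem$network
  desired <- lapply(seq_along(problem$desired), function(i) {
    if (is.na(problem$desired[i])) "-" else unname(problem$desired[i])
  })
  names(desired) <- net$internal
  yaml::write_yaml(list(
    tau = problem$tau,
    externals = as.list(net$external),
    initial = as.list(problem$initial),
    desired = desired
  ), path)
  invisible(path)
}

#' Read / write a control sequence as a TSV table
#'
#' Rows are time steps t = 0..tau-1, columns the external nodes. A file
#' with tau + 1 rows is accepted with a warning and its final row ignored
#' (an assignment at the horizon cannot influence the state there).
#'
#' @param path file path.
#' @param network a [boolean_network()].
#' @param tau expected horizon.
#' @return A tau x m integer matrix.
#' @export
read_control_sequence <- function(path, network, tau) {
  if (!file.exists(path)) stop("sequence file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  as_control_matrix(as.matrix(tab), network, tau)
}

#' @rdname read_control_sequence
#' @param controls a tau x m control matrix.
#' @export
write_control_sequence <- function(controls, path) {
  utils::write.table(controls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
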