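#' Boolean update-function expressions
#'
#' Update rules of a Boolean network are abstract syntax trees over the
#' operators AND, OR and NOT, node-name references and the literals 0/1.
#' Trees are plain lists with an `op` field (`"and"`, `"or"`, `"not"`,
#' `"var"`, `"const"`); `and`/`or` carry two or more children in `args`,
#' `not` exactly one, `var` a `name` and `const` a `value`.
#'
#' @name boolean-expressions
NULL

bexpr <- function(op, ...) {
  node <- list(op = op, ...)
  class(node) <- "boolean_expression"
  node
}

#' Build expression nodes programmatically
#'
#' Constructors for the five node kinds. `bexpr_and`/`bexpr_or` require at
#' least two children, `bexpr_not` exactly one.
#'
#' @param ... child expressions (for `bexpr_and`/`bexpr_or`).
#' @param x a child expression.
#' @param name a node name (character scalar).
#' @param value a bit, 0 or 1.
#' @return A `boolean_expression`.
#' @export
bexpr_and <- function(...) {
  args <- list(...)
  if (length(args) < 2L) stop("AND needs at least two children")
  bexpr("and", args = args)
}

#' @rdname bexpr_and
#' @export
bexpr_or <- function(...) {
  args <- list(...)
  if (length(args) < 2L) stop("OR needs at least two children")
  bexpr("or", args = args)
}

#' @rdname bexpr_and
#' @export
bexpr_not <- function(x) bexpr("not", args = list(x))

#' @rdname bexpr_and
#' @export
bexpr_var <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  bexpr("var", name = name)
}

#' @rdname bexpr_and
#' @export
bexpr_const <- function(value) {
  value <- as.integer(value)
  stopifnot(value %in% c(0L, 1L))
  bexpr("const", value = value)
}

## ---- tokenizer -------------------------------------------------------------

## Tokens: identifiers [A-Za-z][A-Za-z0-9_-]*, literals 0/1, operators
## & | ! (ASCII) or their typeset forms, parentheses.  Each token keeps its
## 1-based character position for error messages.
tokenize_expression <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  op_map <- c("&" = "and", "∧" = "and", "*" = "and",
              "|" = "or",  "∨" = "or",  "+" = "or",
              "!" = "not", "¬" = "not", "~" = "not")
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, pos = i)
      i <- i + 1L
    } else if (ch %in% names(op_map)) {
      toks[[length(toks) + 1L]] <- list(type = op_map[[ch]], pos = i)
      i <- i + 1L
    } else if (ch %in% c("0", "1")) {
      toks[[length(toks) + 1L]] <- list(type = "const", value = as.integer(ch), pos = i)
      i <- i + 1L
    } else if (grepl("^[A-Za-z]$", ch)) {
      j <- i
      while (j < n && grepl("^[A-Za-z0-9_-]$", chars[j + 1L])) j <- j + 1L
      toks[[length(toks) + 1L]] <- list(
        type = "ident", value = paste(chars[i:j], collapse = ""), pos = i)
      i <- j + 1L
    } else {
      stop(sprintf("syntax error at position %d: unexpected character '%s'", i, ch),
           call. = FALSE)
    }
  }
  toks
}

## ---- recursive-descent parser ---------------------------------------------

## Grammar (precedence NOT > AND > OR):
##   or      := and ( '|' and )*
##   and     := unary ( '&' unary )*
##   unary   := '!' unary | primary
##   primary := ident | 0 | 1 | '(' or ')'

#' Parse a boolean formula
#'
#' Parses the plain-text formula dialect used in network files: operators
#' `&` (AND), `|` (OR), `!` (NOT) with precedence `!` > `&` > `|`,
#' parentheses, the literals `0`/`1`, and identifiers matching
#' `[A-Za-z][A-Za-z0-9_-]*`. The typeset operator glyphs (AND/OR/NOT symbols)
#' are accepted as synonyms. References to undeclared nodes are not checked
#' here; that is deferred to network validation.
#'
#' @param text a formula string, e.g. `"EN & !CIR & U3"`.
#' @return A `boolean_expression` AST.
#' @examples
#' parse_boolean_expression("EN & !CIR & U3")
#' @export
parse_boolean_expression <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- tokenize_expression(text)
  if (length(toks) == 0L) stop("syntax error: empty expression", call. = FALSE)
  state <- new.env(parent = emptyenv())
  state$toks <- toks
  state$i <- 1L

  peek <- function() if (state$i <= length(state$toks)) state$toks[[state$i]] else NULL
  advance <- function() { t <- peek(); state$i <- state$i + 1L; t }
  fail <- function(tok, what) {
    pos <- if (is.null(tok)) nchar(text) + 1L else tok$pos
    stop(sprintf("syntax error at position %d: expected %s", pos, what), call. = FALSE)
  }

  parse_or <- function() {
    parts <- list(parse_and())
    while (!is.null(peek()) && peek()$type == "or") {
      advance()
      parts[[length(parts) + 1L]] <- parse_and()
    }
    if (length(parts) == 1L) parts[[1L]] else bexpr("or", args = parts)
  }
  parse_and <- function() {
    parts <- list(parse_unary())
    while (!is.null(peek()) && peek()$type == "and") {
      advance()
      parts[[length(parts) + 1L]] <- parse_unary()
    }
    if (length(parts) == 1L) parts[[1L]] else bexpr("and", args = parts)
  }
  parse_unary <- function() {
    tok <- peek()
    if (!is.null(tok) && tok$type == "not") {
      advance()
      bexpr("not", args = list(parse_unary()))
    } else {
      parse_primary()
    }
  }
  parse_primary <- function() {
    tok <- advance()
    if (is.null(tok)) fail(tok, "an operand")
    switch(tok$type,
      ident = bexpr_var(tok$value),
      const = bexpr_const(tok$value),
      "(" = {
        inner <- parse_or()
        close <- advance()
        if (is.null(close) || close$type != ")") fail(close, "')'")
        inner
      },
      fail(tok, "an operand")
    )
  }

  out <- parse_or()
  left <- peek()
  if (!is.null(left)) {
    stop(sprintf("syntax error at position %d: unexpected trailing input", left$pos),
         call. = FALSE)
  }
  out
}

#' Evaluate a boolean expression under a total assignment
#'
#' @param expr a `boolean_expression`.
#' @param assignment a named vector (or list) mapping node names to bits;
#'   must cover every variable referenced in `expr`.
#' @return 0 or 1 (integer).
#' @examples
#' e <- parse_boolean_expression("CI & SMO")
#' evaluate_expression(e, c(CI = 1, SMO = 1))
#' @export
evaluate_expression <- function(expr, assignment = c()) {
  assignment <- unlist(assignment)
  switch(expr$op,
    const = expr$value,
    var = {
      v <- assignment[expr$name]
      if (length(v) != 1L || is.na(v)) {
        stop(sprintf("no value supplied for node '%s'", expr$name), call. = FALSE)
      }
      as.integer(v)
    },
    not = 1L - evaluate_expression(expr$args[[1L]], assignment),
    and = {
      for (a in expr$args) if (evaluate_expression(a, assignment) == 0L) return(0L)
      1L
    },
    or = {
      for (a in expr$args) if (evaluate_expression(a, assignment) == 1L) return(1L)
      0L
    },
    stop("unknown expression node kind: ", expr$op)
  )
}

#' Variables referenced in an expression
#'
#' @param expr a `boolean_expression`.
#' @return Character vector of distinct node names, in first-occurrence order.
#' @export
expression_vars <- function(expr) {
  switch(expr$op,
    const = character(),
    var = expr$name,
    unique(unlist(lapply(expr$args, expression_vars)))
  )
}

#' Render an expression back to formula text
#'
#' Emits the ASCII dialect (`& | !`), parenthesizing only where precedence
#' requires it; `parse_boolean_expression(render_expression(e))` has the same
#' truth table as `e`.
#'
#' @param expr a `boolean_expression`.
#' @return A formula string.
#' @export
render_expression <- function(expr) {
  prec <- c(or = 1L, and = 2L, not = 3L, var = 4L, const = 4L)
  wrap <- function(child, parent_prec) {
    s <- render_expression(child)
    if (prec[[child$op]] < parent_prec) paste0("(", s, ")") else s
  }
  switch(expr$op,
    const = as.character(expr$value),
    var = expr$name,
    not = paste0("!", wrap(expr$args[[1L]], prec[["not"]])),
    and = paste(vapply(expr$args, wrap, "", prec[["and"]]), collapse = " & "),
    or = paste(vapply(expr$args, wrap, "", prec[["or"]]), collapse = " | ")
  )
}

#' @export
format.boolean_expression <- function(x, ...) render_expression(x)

#' @export
print.boolean_expression <- function(x, ...) {
  cat(render_expression(x), "\n")
  invisible(x)
}

## Truth table of an expression over an explicit variable ordering; used by
## round-trip tests and the compiled simulator.
expression_truth_table <- function(expr, vars) {
  k <- length(vars)
  n_rows <- bitwShiftL(1L, k)
  tt <- integer(n_rows)
  for (r in seq_len(n_rows) - 1L) {
    bits <- bitwAnd(bitwShiftR(r, seq_len(k) - 1L), 1L)
    names(bits) <- vars
    tt[r + 1L] <- evaluate_expression(expr, bits)
  }
  tt
}
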