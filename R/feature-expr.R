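#' Pharmacophore feature kinds
#'
#' The closed set of primitive feature kinds used throughout the package:
#' \code{Aro} (aromatic center), \code{Hyd} (hydrophobic center), \code{Acc}
#' (hydrogen-bond acceptor), \code{Don} (hydrogen-bond donor) and \code{ML}
#' (metal ligator, e.g. a heme-iron coordinating atom).
#'
#' @format A character vector of length 5.
#' @export
FEATURE_KINDS <- c("Aro", "Hyd", "Acc", "Don", "ML")

## ---- feature-type expressions -------------------------------------------
##
## A feature-type expression is a boolean formula over the five kinds with
## "|" (OR) and "&" (AND); "&" binds tighter than "|", parentheses override.
## Internal representation: either list(kind = <chr>) for a leaf, or
## list(op = "or"/"and", args = list(...)). Same-operator nesting is
## flattened so that canonical serialization round-trips.

tokenize_expr <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else if (ch %in% c("|", "&", "(", ")")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch, pos = i)
      i <- i + 1L
    } else {
      m <- regmatches(substr(text, i, n), regexpr("^[A-Za-z]+", substr(text, i, n)))
      if (length(m) == 0L || !(m %in% FEATURE_KINDS)) {
        stop(sprintf("feature expression parse error at position %d in %s: expected one of %s",
                     i, dQuote(text), paste(FEATURE_KINDS, collapse = ", ")),
             call. = FALSE)
      }
      tokens[[length(tokens) + 1L]] <- list(type = "kind", kind = m, pos = i)
      i <- i + nchar(m)
    }
  }
  tokens
}

#' Parse a feature-type expression
#'
#' Parses strings such as \code{"Aro|Hyd"} or \code{"ML&(Acc|Don)"} into an
#' expression tree. \code{"&"} binds tighter than \code{"|"}; parentheses
#' group. Leaves must be one of \code{\link{FEATURE_KINDS}}.
#'
#' @param text a single non-empty string.
#' @return An object of class \code{feature_expr}.
#' @examples
#' parse_type_expr("ML&(Acc|Don)")
#' @export
parse_type_expr <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("feature expression must be a single non-empty string", call. = FALSE)
  tokens <- tokenize_expr(text)
  pos <- 1L

  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  take <- function() { tk <- tokens[[pos]]; pos <<- pos + 1L; tk }
  fail <- function(tk, what) {
    at <- if (is.null(tk)) nchar(text) + 1L else tk$pos
    stop(sprintf("feature expression parse error at position %d in %s: %s",
                 at, dQuote(text), what), call. = FALSE)
  }

  parse_atom <- function() {
    tk <- peek()
    if (is.null(tk)) fail(tk, "unexpected end of input")
    if (tk$type == "kind") { take(); return(list(kind = tk$kind)) }
    if (tk$type == "(") {
      take()
      e <- parse_or()
      cl <- peek()
      if (is.null(cl) || cl$type != ")") fail(cl, "expected ')'")
      take()
      return(e)
    }
    fail(tk, sprintf("unexpected '%s'", tk$type))
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (!is.null(peek()) && peek()$type == "&") {
      take()
      args[[length(args) + 1L]] <- parse_atom()
    }
    if (length(args) == 1L) args[[1L]] else flatten_node("and", args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (!is.null(peek()) && peek()$type == "|") {
      take()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) args[[1L]] else flatten_node("or", args)
  }

  expr <- parse_or()
  if (!is.null(peek())) fail(peek(), sprintf("unexpected '%s'", peek()$type))
  structure(expr, class = "feature_expr")
}

flatten_node <- function(op, args) {
  out <- list()
  for (a in args) {
    if (!is.null(a$op) && a$op == op) out <- c(out, a$args)
    else out[[length(out) + 1L]] <- a
  }
  list(op = op, args = out)
}

#' Serialize a feature-type expression to canonical text
#'
#' Inverse of \code{\link{parse_type_expr}} on canonical forms: OR arguments
#' are joined with \code{"|"}, AND arguments with \code{"&"}, and an OR node
#' under an AND is parenthesized.
#'
#' @param x a \code{feature_expr}.
#' @param ... unused.
#' @return A single string.
#' @export
format.feature_expr <- function(x, ...) expr_to_text(unclass(x))

expr_to_text <- function(node) {
  if (!is.null(node$kind)) return(node$kind)
  parts <- vapply(node$args, function(a) {
    s <- expr_to_text(a)
    if (node$op == "and" && !is.null(a$op) && a$op == "or") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = if (node$op == "or") "|" else "&")
}

#' @export
print.feature_expr <- function(x, ...) {
  cat("<feature_expr> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Evaluate a feature-type expression against a set of kinds
#'
#' @param expr a \code{feature_expr} (or a string, parsed on the fly).
#' @param kinds character vector of perceived feature kinds (may be empty).
#' @return \code{TRUE} if the kind set satisfies the expression.
#' @examples
#' expr_satisfied(parse_type_expr("ML&(Acc|Don)"), c("ML", "Don"))
#' @export
expr_satisfied <- function(expr, kinds) {
  if (is.character(expr)) expr <- parse_type_expr(expr)
  stopifnot(inherits(expr, "feature_expr") || is.list(expr))
  bad <- setdiff(kinds, FEATURE_KINDS)
  if (length(bad))
    stop("unknown feature kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  eval_node(unclass(expr), kinds)
}

eval_node <- function(node, kinds) {
  if (!is.null(node$kind)) return(node$kind %in% kinds)
  vals <- vapply(node$args, eval_node, logical(1), kinds = kinds)
  if (node$op == "or") any(vals) else all(vals)
}

## All leaves of an expression (the kinds it mentions), in order of appearance.
expr_leaves <- function(expr) {
  node <- unclass(expr)
  rec <- function(n) {
    if (!is.null(n$kind)) return(n$kind)
    unlist(lapply(n$args, rec))
  }
  unique(rec(node))
}

## Minimal satisfying kind sets of a (monotone) expression, found by
## truth-table enumeration over the kinds the expression mentions.
minimal_satisfying_sets <- function(expr) {
  leaves <- expr_leaves(expr)
  k <- length(leaves)
  sets <- list()
  for (mask in seq_len(2^k) - 1L) {
    sel <- leaves[bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L]
    if (expr_satisfied(expr, sel)) sets[[length(sets) + 1L]] <- sel
  }
  is_minimal <- vapply(seq_along(sets), function(i) {
    !any(vapply(seq_along(sets), function(j) {
      j != i && length(sets[[j]]) < length(sets[[i]]) && all(sets[[j]] %in% sets[[i]])
    }, logical(1)))
  }, logical(1))
  sets[is_minimal]
}
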