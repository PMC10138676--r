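# Gene-protein-reaction (GPR) rules.
#
# A GPR is a boolean expression over gene identifiers: AND joins subunits of a
# complex (all required), OR joins isozymes (any suffices). AND binds tighter
# than OR; parentheses override. The parser produces a small AST of nested
# lists: list(op = "gene", id = ...) at the leaves and
# list(op = "and"/"or", args = list(...)) at internal nodes. An empty rule
# parses to NULL, meaning the reaction needs no gene (spontaneous or
# orphan-annotated) and is always available.

#' Parse a GPR rule string
#'
#' @param rule a GPR string, e.g. `"(bsu1 and bsu2) or bsu3"`. `AND`/`OR`,
#'   `&`/`|` and any case are accepted. Empty/`NA` rules return `NULL`.
#' @return an AST (nested list) or `NULL` for an empty rule.
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0 || is.na(rule) ||
      !nzchar(trimws(rule))) {
    return(NULL)
  }
  rule <- gsub("&&|&", " and ", rule)
  rule <- gsub("\\|\\||\\|", " or ", rule)
  toks <- regmatches(rule, gregexpr("\\(|\\)|[^\\s()]+", rule, perl = TRUE))[[1]]
  pos <- 1L

  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  is_op <- function(t, op) !is.na(t) && tolower(t) == op

  parse_expr <- function() {
    args <- list(parse_term())
    while (is_op(peek(), "or")) {
      advance()
      args <- c(args, list(parse_term()))
    }
    if (length(args) == 1) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (is_op(peek(), "and")) {
      advance()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- advance()
    if (is.na(t)) abort("malformed GPR: unexpected end of rule", class = "gemkit_gpr_error")
    if (t == "(") {
      e <- parse_expr()
      if (!identical(advance(), ")")) {
        abort("malformed GPR: missing closing parenthesis", class = "gemkit_gpr_error")
      }
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) {
      abort(paste0("malformed GPR: unexpected token '", t, "'"),
            class = "gemkit_gpr_error")
    }
    list(op = "gene", id = t)
  }

  ast <- parse_expr()
  if (pos <= length(toks)) {
    abort(paste0("malformed GPR: trailing token '", peek(), "'"),
          class = "gemkit_gpr_error")
  }
  ast
}

#' Evaluate a GPR rule against a set of present genes
#'
#' @param gpr a parsed AST from [parse_gpr()] or a rule string. `NULL`/empty
#'   rules evaluate to `TRUE` (the reaction is retained).
#' @param present_genes character vector of genes present in the strain.
#' @return logical scalar: is the reaction available?
#' @examples
#' evaluate_gpr("(g1 and g2) or g3", c("g3"))
#' @export
evaluate_gpr <- function(gpr, present_genes) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  if (is.null(gpr)) return(TRUE)
  eval_node <- function(node) {
    switch(node$op,
      gene = node$id %in% present_genes,
      and = all(vapply(node$args, eval_node, logical(1))),
      or = any(vapply(node$args, eval_node, logical(1))),
      abort("malformed GPR AST", class = "gemkit_gpr_error")
    )
  }
  eval_node(gpr)
}

#' Genes referenced by a GPR rule
#'
#' @inheritParams evaluate_gpr
#' @return character vector of unique gene ids (empty for an empty rule).
#' @export
gpr_genes <- function(gpr) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  if (is.null(gpr)) return(character(0))
  collect <- function(node) {
    if (node$op == "gene") return(node$id)
    unlist(lapply(node$args, collect))
  }
  unique(collect(gpr))
}

# deparse an AST back to a string; compound children are parenthesised so the
# tree structure survives a reparse exactly
deparse_gpr <- function(gpr) {
  if (is.null(gpr)) return("")
  dep <- function(node, top = FALSE) {
    if (node$op == "gene") return(node$id)
    sep <- if (node$op == "and") " and " else " or "
    s <- paste(vapply(node$args, dep, character(1)), collapse = sep)
    if (top) s else paste0("(", s, ")")
  }
  dep(gpr, top = TRUE)
}
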