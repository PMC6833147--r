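#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules encode which gene products a reaction requires as a boolean
#' expression over gene identifiers: `and` joins subunits of a complex (all
#' required), `or` joins isoenzymes (any suffices). `and` binds tighter than
#' `or`, and parentheses group. Keywords are case-insensitive; any other
#' whitespace-delimited token (or parenthesis-delimited) is a gene id.
#'
#' @param text a GPR rule string, e.g. `"g1 and g2 or g3"`. `NA` or an
#'   all-whitespace string yields `NULL` (no gene association).
#' @return A `gpr` object: a nested list of nodes of type `"leaf"`, `"and"`
#'   or `"or"` (n-ary; same-type children are flattened), or `NULL`.
#' @examples
#' parse_gpr("g1 and g2 or g3")
#' render_gpr(parse_gpr("(g1 or g2) and g3"))
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0) return(NULL)
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(trimws(text))) return(NULL)

  # tokenize, remembering character positions for error messages
  toks <- list()
  i <- 1L
  nc <- nchar(text)
  while (i <= nc) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(t = ch, pos = i)
      i <- i + 1L
      next
    }
    j <- i
    while (j <= nc && !grepl("^[\\s()]$", substr(text, j, j), perl = TRUE)) j <- j + 1L
    word <- substr(text, i, j - 1L)
    kind <- switch(tolower(word), "and" = "AND", "or" = "OR", "ID")
    toks[[length(toks) + 1L]] <- list(t = kind, v = word, pos = i)
    i <- j
  }
  if (!length(toks)) return(NULL)

  k <- 1L
  peek <- function() if (k <= length(toks)) toks[[k]] else NULL
  advance <- function() { tk <- toks[[k]]; k <<- k + 1L; tk }
  fail <- function(msg, pos) {
    stop(sprintf("GPR parse error at position %d: %s (in \"%s\")", pos, msg, text),
         call. = FALSE)
  }

  parse_factor <- function() {
    tk <- peek()
    if (is.null(tk)) fail("unexpected end of rule", nc + 1L)
    if (tk$t == "(") {
      open <- advance()
      node <- parse_or()
      tk2 <- peek()
      if (is.null(tk2) || tk2$t != ")") fail("unbalanced parenthesis", open$pos)
      advance()
      return(node)
    }
    if (tk$t == "ID") {
      advance()
      return(gpr_leaf(tk$v))
    }
    fail(sprintf("unexpected token \"%s\"", tk$v %||% tk$t), tk$pos)
  }
  parse_and <- function() {
    kids <- list(parse_factor())
    while (!is.null(tk <- peek()) && tk$t == "AND") {
      advance()
      kids[[length(kids) + 1L]] <- parse_factor()
    }
    if (length(kids) == 1L) kids[[1L]] else gpr_node("and", kids)
  }
  parse_or <- function() {
    kids <- list(parse_and())
    while (!is.null(tk <- peek()) && tk$t == "OR") {
      advance()
      kids[[length(kids) + 1L]] <- parse_and()
    }
    if (length(kids) == 1L) kids[[1L]] else gpr_node("or", kids)
  }

  node <- parse_or()
  if (!is.null(tk <- peek())) {
    fail(sprintf("unexpected token \"%s\" after end of expression", tk$v %||% tk$t), tk$pos)
  }
  node
}

gpr_leaf <- function(gene) structure(list(type = "leaf", gene = gene), class = "gpr")

gpr_node <- function(type, children) {
  # flatten nested nodes of the same type so the AST is canonical (n-ary)
  flat <- list()
  for (ch in children) {
    if (inherits(ch, "gpr") && ch$type == type) {
      flat <- c(flat, ch$children)
    } else {
      flat[[length(flat) + 1L]] <- ch
    }
  }
  structure(list(type = type, children = flat), class = "gpr")
}

#' Render a GPR tree to its canonical string
#'
#' Uses lowercase `and`/`or` and full parenthesisation of every non-leaf
#' node, so `parse_gpr(render_gpr(x))` reproduces `x` exactly.
#'
#' @param gpr a `gpr` object or `NULL`.
#' @return A string, or `NA_character_` for `NULL` (no association).
#' @export
render_gpr <- function(gpr) {
  if (is.null(gpr)) return(NA_character_)
  stopifnot(inherits(gpr, "gpr"))
  if (gpr$type == "leaf") return(gpr$gene)
  inner <- vapply(gpr$children, render_gpr, character(1))
  paste0("(", paste(inner, collapse = paste0(" ", gpr$type, " ")), ")")
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", render_gpr(x), "\n", sep = "")
  invisible(x)
}

#' Evaluate a GPR rule against a set of inactive genes
#'
#' A leaf is `TRUE` iff its gene is not in `inactive`; `and`/`or` nodes are
#' evaluated as boolean algebra. A `NULL` (absent) rule is `TRUE`: reactions
#' without gene association (spontaneous reactions) are never deactivated by
#' expression evidence.
#'
#' @param gpr a `gpr` object or `NULL`.
#' @param inactive character vector of inactive gene ids.
#' @return `TRUE` if the reaction can still be catalysed, else `FALSE`.
#' @examples
#' evaluate_gpr(parse_gpr("g1 and g2 or g3"), inactive = "g2")
#' @export
evaluate_gpr <- function(gpr, inactive = character()) {
  if (is.null(gpr)) return(TRUE)
  stopifnot(inherits(gpr, "gpr"))
  switch(gpr$type,
    leaf = !(gpr$gene %in% inactive),
    and  = all(vapply(gpr$children, evaluate_gpr, logical(1), inactive = inactive)),
    or   = any(vapply(gpr$children, evaluate_gpr, logical(1), inactive = inactive)),
    stop("invalid gpr node type: ", gpr$type)
  )
}

#' List the genes appearing in a GPR rule
#'
#' @param gpr a `gpr` object or `NULL`.
#' @return Character vector of unique gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character())
  if (gpr$type == "leaf") return(gpr$gene)
  unique(unlist(lapply(gpr$children, gpr_genes)))
}
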