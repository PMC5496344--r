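# Gene-protein-reaction (GPR) boolean rules.
#
# Rules are stored as strings in the common COBRA dialect, e.g.
# "(g1 and g2) or g3". A rule evaluates to active when at least one
# minimal gene set it encodes is fully present.

gpr_tokenize <- function(x) {
  x <- gsub("&&|&", " and ", x)
  x <- gsub("\\|\\||\\|", " or ", x)
  x <- gsub("([()])", " \\1 ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a GPR rule into a boolean expression tree
#'
#' Grammar: `expr := term ("or" term)*`, `term := factor ("and" factor)*`,
#' `factor := gene | "(" expr ")"`. `and` binds tighter than `or`;
#' `&`/`|` synonyms and arbitrary case are accepted.
#'
#' @param x rule string; `""`/`NA` yield `NULL` (no gene requirement).
#' @return A nested list with elements `op` (`"and"`/`"or"`) and `args`,
#'   or a bare gene id string at the leaves.
#' @export
gpr_parse <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(trimws(x))) return(NULL)
  toks <- gpr_tokenize(x)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("GPR parse error: unexpected end in '", x, "'")
    if (t == "(") {
      take()
      e <- parse_expr()
      if (!identical(peek(), ")")) stop("GPR parse error: missing ')' in '", x, "'")
      take()
      return(e)
    }
    if (tolower(t) %in% c("and", "or", ")"))
      stop("GPR parse error: unexpected '", t, "' in '", x, "'")
    take()
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      args <- c(args, list(parse_term()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  out <- parse_expr()
  if (pos <= length(toks))
    stop("GPR parse error: trailing '", toks[pos], "' in '", x, "'")
  out
}

#' Serialize a parsed GPR tree back to a rule string
#'
#' Inner nodes are parenthesized, so `gpr_parse(gpr_serialize(t))`
#' reproduces the tree exactly.
#'
#' @param tree result of [gpr_parse()].
#' @return Rule string (`""` for `NULL`).
#' @export
gpr_serialize <- function(tree) {
  if (is.null(tree)) return("")
  if (is.character(tree)) return(tree)
  parts <- vapply(tree$args, function(a) {
    if (is.character(a)) a else paste0("(", gpr_serialize(a), ")")
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}

#' Evaluate a GPR rule under gene deletions
#'
#' @param x rule string or parsed tree.
#' @param absent character vector of deleted gene ids.
#' @return `TRUE` if the reaction remains catalyzed, `FALSE` otherwise.
#'   Rules with no genes are always active.
#' @export
gpr_eval <- function(x, absent = character()) {
  tree <- if (is.character(x) && length(x) == 1L && !x %in% absent)
    gpr_parse(x) else x
  rec <- function(t) {
    if (is.null(t)) return(TRUE)
    if (is.character(t)) return(!(t %in% absent))
    vals <- vapply(t$args, rec, logical(1))
    if (t$op == "and") all(vals) else any(vals)
  }
  rec(tree)
}

#' Genes referenced by a GPR rule
#'
#' @param x rule string or parsed tree.
#' @return Character vector of gene ids (empty for no rule).
#' @export
gpr_genes <- function(x) {
  tree <- if (is.character(x)) gpr_parse(x) else x
  rec <- function(t) {
    if (is.null(t)) return(character())
    if (is.character(t)) return(t)
    unique(unlist(lapply(t$args, rec)))
  }
  rec(tree)
}
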