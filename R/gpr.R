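#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers with the keywords
#' `AND` (enzyme complex: every subunit required) and `OR` (isozymes: any one
#' suffices), case-insensitive, with parentheses. `AND` binds tighter than
#' `OR`, matching common SBML-FBC text renderings. The empty string means
#' "no gene association" and always evaluates to active.
#'
#' @param rule Character scalar, e.g. `"(g1 and g2) or g3"`, or an already
#'   parsed rule (returned unchanged).
#' @return A parse tree of class `gpr_rule`: either `NULL` (no association),
#'   a character scalar (single gene leaf), or a list with elements `op`
#'   (`"and"`/`"or"`) and `args` (list of subtrees).
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' @export
parse_gpr <- function(rule) {
  if (inherits(rule, "gpr_rule")) return(rule)
  if (is.null(rule) || length(rule) == 0 || is.na(rule) || !nzchar(trimws(rule))) {
    return(structure(list(tree = NULL, string = ""), class = "gpr_rule"))
  }
  stopifnot(is.character(rule), length(rule) == 1)
  toks <- gpr_tokenize(rule)
  env <- new.env(parent = emptyenv())
  env$toks <- toks$token
  env$pos0 <- toks$position
  env$i <- 1L
  tree <- gpr_parse_or(env, rule)
  if (env$i <= length(env$toks)) {
    stop(sprintf("GPR parse error in %s: unexpected token '%s' at position %d",
                 sQuote(rule), env$toks[env$i], env$pos0[env$i]), call. = FALSE)
  }
  structure(list(tree = tree, string = rule), class = "gpr_rule")
}

gpr_tokenize <- function(rule) {
  token <- character(0); position <- integer(0)
  chars <- strsplit(rule, "", fixed = TRUE)[[1]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      token <- c(token, ch); position <- c(position, i); i <- i + 1L; next
    }
    j <- i
    while (j <= length(chars) && !grepl("^[\\s()]$", chars[j], perl = TRUE)) j <- j + 1L
    token <- c(token, paste(chars[i:(j - 1L)], collapse = ""))
    position <- c(position, i)
    i <- j
  }
  list(token = token, position = position)
}

gpr_peek <- function(env) if (env$i <= length(env$toks)) env$toks[env$i] else NA_character_

gpr_parse_or <- function(env, rule) {
  args <- list(gpr_parse_and(env, rule))
  while (!is.na(tk <- gpr_peek(env)) && tolower(tk) == "or") {
    env$i <- env$i + 1L
    args <- c(args, list(gpr_parse_and(env, rule)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gpr_parse_and <- function(env, rule) {
  args <- list(gpr_parse_atom(env, rule))
  while (!is.na(tk <- gpr_peek(env)) && tolower(tk) == "and") {
    env$i <- env$i + 1L
    args <- c(args, list(gpr_parse_atom(env, rule)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(env, rule) {
  tk <- gpr_peek(env)
  if (is.na(tk)) {
    stop(sprintf("GPR parse error in %s: unexpected end of expression", sQuote(rule)),
         call. = FALSE)
  }
  if (tk == "(") {
    env$i <- env$i + 1L
    sub <- gpr_parse_or(env, rule)
    if (is.na(gpr_peek(env)) || gpr_peek(env) != ")") {
      stop(sprintf("GPR parse error in %s: missing ')' at position %d",
                   sQuote(rule), if (env$i <= length(env$pos0)) env$pos0[env$i] else nchar(rule) + 1L),
           call. = FALSE)
    }
    env$i <- env$i + 1L
    return(sub)
  }
  if (tolower(tk) %in% c("and", "or", ")")) {
    stop(sprintf("GPR parse error in %s: unexpected token '%s' at position %d",
                 sQuote(rule), tk, env$pos0[env$i]), call. = FALSE)
  }
  env$i <- env$i + 1L
  tk
}

#' Evaluate a GPR rule under a gene-knockout set
#'
#' A gene leaf is `FALSE` iff the gene is knocked out; `AND` nodes are
#' conjunctions, `OR` nodes disjunctions. An empty rule (no gene
#' association) always evaluates `TRUE`: the reaction stays active.
#'
#' @param rule GPR rule string or `gpr_rule` object.
#' @param knocked_out Character vector of deleted gene ids.
#' @return Logical scalar: is the reaction still catalysable?
#' @examples
#' evaluate_gpr("(g1 and g2) or g3", knocked_out = "g1")   # TRUE: g3 covers
#' evaluate_gpr("(g1 and g2) or g3", knocked_out = c("g1", "g3"))  # FALSE
#' @export
evaluate_gpr <- function(rule, knocked_out = character(0)) {
  rule <- parse_gpr(rule)
  gpr_eval_node(rule$tree, knocked_out)
}

gpr_eval_node <- function(node, knocked_out) {
  if (is.null(node)) return(TRUE)
  if (is.character(node)) return(!(node %in% knocked_out))
  vals <- vapply(node$args, gpr_eval_node, logical(1), knocked_out = knocked_out)
  if (node$op == "and") all(vals) else any(vals)
}

#' Genes referenced by a GPR rule
#'
#' @param rule GPR rule string or `gpr_rule` object.
#' @return Character vector of distinct gene ids (empty for no association).
#' @export
gpr_genes <- function(rule) {
  rule <- parse_gpr(rule)
  unique(gpr_collect_leaves(rule$tree))
}

gpr_collect_leaves <- function(node) {
  if (is.null(node)) return(character(0))
  if (is.character(node)) return(node)
  unlist(lapply(node$args, gpr_collect_leaves), use.names = FALSE)
}

#' @export
format.gpr_rule <- function(x, ...) {
  if (is.null(x$tree)) "" else gpr_deparse(x$tree, top = TRUE)
}

gpr_deparse <- function(node, top = FALSE) {
  if (is.character(node)) return(node)
  parts <- vapply(node$args, function(a) {
    s <- gpr_deparse(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", node$op, " "))
}

#' @export
print.gpr_rule <- function(x, ...) {
  cat("<gpr_rule> ", if (is.null(x$tree)) "(no gene association)" else format(x), "\n", sep = "")
  invisible(x)
}
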