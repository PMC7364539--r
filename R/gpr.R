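#' Parse a gene-protein-reaction (GPR) boolean rule
#'
#' GPR rules link genes to the reaction they catalyse: `and` joins subunits
#' of a complex (all required), `or` joins isozymes (any suffices).  The
#' grammar accepted is identifiers combined with `and`/`or` (case
#' insensitive; `&`/`|` also accepted) and parentheses, e.g.
#' `"(Msil_1262 and Msil_1263) or Msil_1651"`.
#'
#' @param text GPR rule as a single string.  `NA`, `NULL` or an
#'   empty/whitespace string denote "no gene association" and parse to
#'   `NULL` (the reaction is treated as spontaneous/orphan and always
#'   active).
#' @return An expression tree: `NULL`, a gene id (character scalar), or a
#'   list with elements `op` (`"and"`/`"or"`) and `args` (list of subtrees).
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0) return(NULL)
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- gpr_tokenise(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("malformed GPR rule: unexpected token '", st$toks[st$pos],
         "' in \"", text, "\"", call. = FALSE)
  }
  tree
}

gpr_tokenise <- function(text) {
  text <- gsub("&&?", " and ", text)
  text <- gsub("\\|\\|?", " or ", text)
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(tok <- gpr_peek(st)) && tolower(tok) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(tok <- gpr_peek(st)) && tolower(tok) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1) args[[1]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tok <- gpr_peek(st)
  if (is.na(tok)) stop("malformed GPR rule: unexpected end of expression", call. = FALSE)
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")")
      stop("malformed GPR rule: missing closing parenthesis", call. = FALSE)
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or"))
    stop("malformed GPR rule: unexpected token '", tok, "'", call. = FALSE)
  st$pos <- st$pos + 1L
  tok
}

#' Evaluate a GPR rule under a set of gene deletions
#'
#' Deleted genes are set to FALSE, all other genes to TRUE, and the boolean
#' expression is evaluated.  A reaction with no GPR is always active.
#'
#' @param gpr A GPR rule string or a tree from [parse_gpr()].
#' @param deleted Character vector of deleted gene ids.
#' @return `TRUE` if the reaction retains catalytic support, else `FALSE`.
#' @examples
#' evaluate_gpr("(g1 and g2) or g3", deleted = "g1")  # TRUE: g3 rescues
#' evaluate_gpr("Msil_1651", deleted = "Msil_1651")   # FALSE
#' @export
evaluate_gpr <- function(gpr, deleted = character()) {
  tree <- if (is.character(gpr) && length(gpr) == 1 && !is.list(gpr)) parse_gpr(gpr) else gpr
  gpr_eval_tree(tree, deleted)
}

gpr_eval_tree <- function(tree, deleted) {
  if (is.null(tree)) return(TRUE)
  if (is.character(tree)) return(!(tree %in% deleted))
  vals <- vapply(tree$args, gpr_eval_tree, logical(1), deleted = deleted)
  if (tree$op == "and") all(vals) else any(vals)
}

#' Genes referenced by a GPR rule
#'
#' @param gpr A GPR rule string or parsed tree.
#' @return Character vector of unique gene ids (empty for spontaneous
#'   reactions).
#' @export
gpr_genes <- function(gpr) {
  tree <- if (is.character(gpr) && length(gpr) == 1 && !is.list(gpr)) parse_gpr(gpr) else gpr
  if (is.null(tree)) return(character())
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' Deparse a GPR tree back to rule text
#'
#' @param tree Tree from [parse_gpr()] (or a rule string, returned as is).
#' @return A GPR rule string, or `NA` for an empty rule.
#' @export
deparse_gpr <- function(tree) {
  if (is.null(tree)) return(NA_character_)
  if (is.character(tree) && !is.list(tree)) return(tree)
  parts <- vapply(tree$args, function(a) {
    s <- deparse_gpr(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}
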