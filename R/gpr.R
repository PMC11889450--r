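#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers that state which
#' gene products are needed for a reaction to be catalysed: \code{and} joins
#' subunits of a complex, \code{or} joins isoenzymes. The grammar accepts
#' \code{and}/\code{or} keywords (case-insensitive) and parentheses; without
#' parentheses \code{and} binds tighter than \code{or}, the common convention
#' in SBML-FBC models.
#'
#' The returned rule is either a gene id (a leaf, a length-one character
#' vector) or a list with elements \code{op} (\code{"and"} or \code{"or"})
#' and \code{children}. Nested nodes with the same operator are flattened so
#' every internal node has at least two children.
#'
#' @param text the rule as text, e.g. \code{"(g1 and g2) or g3"}.
#' @return a GPR rule tree, or \code{NULL} for empty/whitespace-only input.
#' @examples
#' r <- parseGpr("g1 and g2 or g3")
#' gprToString(r)   # "(g1 and g2) or g3"
#' @export
parseGpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- .gprTokens(text)
  if (nrow(toks) == 0L) return(NULL)
  env <- new.env(parent = emptyenv())
  env$toks <- toks
  env$pos <- 1L
  rule <- .gprExpr(env)
  if (env$pos <= nrow(env$toks)) {
    t <- env$toks[env$pos, ]
    stop(sprintf("GPR parse error at position %d: unexpected '%s'",
                 t$at, t$text), call. = FALSE)
  }
  rule
}

.gprTokens <- function(text) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1L) return(data.frame(text = character(), at = integer()))
  len <- attr(m, "match.length")
  data.frame(text = substring(text, m, m + len - 1L), at = as.integer(m),
             stringsAsFactors = FALSE)
}

.gprPeek <- function(env) {
  if (env$pos > nrow(env$toks)) NULL else env$toks[env$pos, ]
}

# expr := term ('or' term)*
.gprExpr <- function(env) {
  kids <- list(.gprTerm(env))
  repeat {
    t <- .gprPeek(env)
    if (is.null(t) || tolower(t$text) != "or") break
    env$pos <- env$pos + 1L
    kids <- c(kids, list(.gprTerm(env)))
  }
  .gprNode("or", kids)
}

# term := factor ('and' factor)*
.gprTerm <- function(env) {
  kids <- list(.gprFactor(env))
  repeat {
    t <- .gprPeek(env)
    if (is.null(t) || tolower(t$text) != "and") break
    env$pos <- env$pos + 1L
    kids <- c(kids, list(.gprFactor(env)))
  }
  .gprNode("and", kids)
}

.gprFactor <- function(env) {
  t <- .gprPeek(env)
  if (is.null(t))
    stop("GPR parse error: unexpected end of rule (dangling operator?)",
         call. = FALSE)
  if (t$text == "(") {
    env$pos <- env$pos + 1L
    inner <- .gprExpr(env)
    t2 <- .gprPeek(env)
    if (is.null(t2) || t2$text != ")")
      stop(sprintf("GPR parse error at position %d: unbalanced parenthesis",
                   t$at), call. = FALSE)
    env$pos <- env$pos + 1L
    return(inner)
  }
  if (t$text == ")")
    stop(sprintf("GPR parse error at position %d: unbalanced ')'", t$at),
         call. = FALSE)
  if (tolower(t$text) %in% c("and", "or"))
    stop(sprintf("GPR parse error at position %d: dangling operator '%s'",
                 t$at, t$text), call. = FALSE)
  env$pos <- env$pos + 1L
  t$text
}

.gprNode <- function(op, kids) {
  # flatten same-op children so internal nodes have >= 2 children
  flat <- list()
  for (k in kids) {
    if (is.list(k) && identical(k$op, op)) flat <- c(flat, k$children)
    else flat <- c(flat, list(k))
  }
  if (length(flat) == 1L) return(flat[[1L]])
  list(op = op, children = flat)
}

#' Render a GPR rule as canonical text
#'
#' Produces a string that reparses to the same tree: \code{and} groups are
#' parenthesised inside \code{or} only where needed.
#'
#' @param rule a rule from [parseGpr()] (or \code{NULL}).
#' @return a character string, or \code{NA_character_} for \code{NULL}.
#' @export
gprToString <- function(rule) {
  if (is.null(rule)) return(NA_character_)
  if (is.character(rule)) return(rule)
  sep <- paste0(" ", rule$op, " ")
  parts <- vapply(rule$children, function(k) {
    s <- gprToString(k)
    # 'and' binds tighter: parenthesise an 'or' child under 'and'
    if (is.list(k) && rule$op == "and" && k$op == "or") paste0("(", s, ")")
    else s
  }, character(1))
  paste(parts, collapse = sep)
}

#' Genes referenced by a GPR rule
#' @param rule a rule from [parseGpr()].
#' @return character vector of unique gene ids (empty for \code{NULL}).
#' @export
gprGenes <- function(rule) {
  if (is.null(rule)) return(character())
  if (is.character(rule)) return(rule)
  unique(unlist(lapply(rule$children, gprGenes)))
}

#' Evaluate a GPR rule against gene-level expression
#'
#' Maps gene values to a reaction-level value with the complex/isoenzyme
#' convention: an \code{and} node takes the minimum of its children (a
#' complex is limited by its scarcest subunit), an \code{or} node the maximum
#' (isoenzymes are interchangeable). Genes absent from the profile are
#' dropped from their parent node; a node whose children are all absent is
#' itself absent, and a rule evaluating to absent returns \code{NA}.
#'
#' @param rule a rule from [parseGpr()] (or \code{NULL}).
#' @param values named numeric vector of gene-level values.
#' @return a numeric value, or \code{NA_real_} when undefined.
#' @export
gprValue <- function(rule, values) {
  if (is.null(rule)) return(NA_real_)
  if (is.character(rule)) {
    v <- values[rule]
    return(if (length(v) == 1L && !is.na(v)) unname(v) else NA_real_)
  }
  kid <- vapply(rule$children, gprValue, numeric(1), values = values)
  kid <- kid[!is.na(kid)]
  if (length(kid) == 0L) return(NA_real_)
  if (rule$op == "and") min(kid) else max(kid)
}
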