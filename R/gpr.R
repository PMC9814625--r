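#' Gene-protein-reaction (GPR) rules
#'
#' A GPR rule is a boolean expression over gene identifiers with `and` / `or`
#' connectives stating which gene products enable a reaction (an `and` models
#' an enzyme complex, an `or` models isozymes). [parse_gpr()] turns a rule
#' string into a tree, [gpr_to_string()] serializes it back, and
#' [evaluate_gpr_presence()] evaluates it against a set of present genes.
#'
#' Internally a rule is either `NULL` (the empty rule: a reaction with no
#' gene requirement, e.g. a transport or exchange reaction), a leaf
#' `list(type = "gene", gene = <id>)`, or an n-ary node
#' `list(type = "and"|"or", args = <list of subtrees>)`. Nested nodes of the
#' same type are flattened, so parsing is canonicalizing: `a or (b or c)`
#' and `(a or b) or c` produce the same tree.
#'
#' @param rule_text A rule string such as `"(g1 and g2) or g3"`. Operators
#'   are case-insensitive; gene ids are any token that is not an operator or
#'   parenthesis. An empty or all-whitespace string yields the empty rule.
#' @return `parse_gpr()` returns a GPR tree (or `NULL` for the empty rule).
#' @examples
#' g <- parse_gpr("(g1 and g2) or g3")
#' gpr_to_string(g)
#' evaluate_gpr_presence(g, c("g3"))
#' evaluate_gpr_presence(g, c("g1"))
#' @export
parse_gpr <- function(rule_text) {
  if (is.null(rule_text) || length(rule_text) == 0L) return(NULL)
  stopifnot(is.character(rule_text), length(rule_text) == 1L)
  if (is.na(rule_text) || !nzchar(trimws(rule_text))) return(NULL)

  toks <- gpr_tokenize(rule_text)
  st <- new.env(parent = emptyenv())
  st$tokens <- toks
  st$pos <- 1L

  tree <- gpr_parse_or(st)
  if (st$pos <= nrow(st$tokens)) {
    cf_abort(
      sprintf(
        "GPR parse error at position %d: unexpected '%s'",
        st$tokens$at[st$pos], st$tokens$text[st$pos]
      ),
      "gpr_parse_error"
    )
  }
  tree
}

gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1L) {
    return(data.frame(text = character(), at = integer(), kind = character()))
  }
  txt <- regmatches(text, gregexpr(pat, text))[[1]]
  low <- tolower(txt)
  kind <- ifelse(txt == "(", "lparen",
    ifelse(txt == ")", "rparen",
      ifelse(low == "and", "and", ifelse(low == "or", "or", "gene"))
    )
  )
  data.frame(text = txt, at = as.integer(m), kind = kind,
             stringsAsFactors = FALSE)
}

gpr_peek <- function(st) {
  if (st$pos > nrow(st$tokens)) NULL else st$tokens$kind[st$pos]
}

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (identical(gpr_peek(st), "or")) {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  gpr_node("or", args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_factor(st))
  while (identical(gpr_peek(st), "and")) {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_factor(st)))
  }
  gpr_node("and", args)
}

gpr_parse_factor <- function(st) {
  k <- gpr_peek(st)
  if (is.null(k)) {
    cf_abort("GPR parse error: unexpected end of rule (dangling operator?)",
             "gpr_parse_error")
  }
  if (k == "lparen") {
    open_at <- st$tokens$at[st$pos]
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (!identical(gpr_peek(st), "rparen")) {
      cf_abort(
        sprintf("GPR parse error: unbalanced '(' opened at position %d", open_at),
        "gpr_parse_error"
      )
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (k == "gene") {
    gene <- trimws(st$tokens$text[st$pos])
    st$pos <- st$pos + 1L
    return(list(type = "gene", gene = gene))
  }
  cf_abort(
    sprintf(
      "GPR parse error at position %d: unexpected '%s'",
      st$tokens$at[st$pos], st$tokens$text[st$pos]
    ),
    "gpr_parse_error"
  )
}

## n-ary node constructor: collapses single-argument nodes and flattens
## nested nodes of the same type, giving every rule one canonical tree.
gpr_node <- function(type, args) {
  flat <- list()
  for (a in args) {
    if (is.list(a) && identical(a$type, type)) {
      flat <- c(flat, a$args)
    } else {
      flat <- c(flat, list(a))
    }
  }
  if (length(flat) == 1L) return(flat[[1L]])
  list(type = type, args = flat)
}

#' @rdname parse_gpr
#' @param gpr A GPR tree as returned by [parse_gpr()].
#' @export
gpr_to_string <- function(gpr) {
  if (is.null(gpr)) return("")
  if (identical(gpr$type, "gene")) return(gpr$gene)
  parts <- vapply(gpr$args, function(a) {
    s <- gpr_to_string(a)
    if (!identical(a$type, "gene")) s <- paste0("(", s, ")")
    s
  }, character(1))
  paste(parts, collapse = paste0(" ", gpr$type, " "))
}

#' @rdname parse_gpr
#' @param present_genes Character vector of gene ids considered present.
#' @return `evaluate_gpr_presence()` returns `TRUE` if the rule is satisfied
#'   by the presence set. The empty rule is always `TRUE` (reactions without
#'   gene requirements are never removed by presence filtering).
#' @export
evaluate_gpr_presence <- function(gpr, present_genes) {
  if (is.null(gpr)) return(TRUE)
  if (identical(gpr$type, "gene")) return(gpr$gene %in% present_genes)
  vals <- vapply(gpr$args, evaluate_gpr_presence, logical(1),
                 present_genes = present_genes)
  if (identical(gpr$type, "and")) all(vals) else any(vals)
}

#' @rdname parse_gpr
#' @return `gpr_genes()` returns the sorted unique gene ids in the rule.
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character())
  if (identical(gpr$type, "gene")) return(gpr$gene)
  sort(unique(unlist(lapply(gpr$args, gpr_genes))))
}

## Abundance semantics of a rule: a complex (and) is limited by its scarcest
## subunit (min), isozymes (or) by the most abundant one (max). Genes absent
## from the abundance vector count as 0. The empty rule returns NA; callers
## substitute a neutral value (see reaction_abundance()).
gpr_abundance <- function(gpr, abundance) {
  if (is.null(gpr)) return(NA_real_)
  if (identical(gpr$type, "gene")) {
    a <- abundance[[gpr$gene]]
    return(if (is.null(a) || is.na(a)) 0 else as.double(a))
  }
  vals <- vapply(gpr$args, gpr_abundance, numeric(1), abundance = abundance)
  if (identical(gpr$type, "and")) min(vals) else max(vals)
}
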