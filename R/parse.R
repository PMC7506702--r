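#' Parse a concept expression
#'
#' Parses the Manchester-syntax subset used for tag annotations: the
#' keywords `and`, `not`, `only`, `min`, `max`, `Thing`, `Nothing`,
#' parentheses and (optionally prefixed) names. Any other OWL construct is
#' rejected, which enforces the ALN fragment at the system boundary. When a
#' terminology is supplied, every class and role name must be declared in
#' it; parsing is whitespace-insensitive and names are case-sensitive.
#'
#' @param text A single string, e.g. `"PDM and Anemia"`.
#' @param tbox Optional [tbox()] used to validate names.
#' @return An `aln_concept`.
#' @examples
#' parse_manchester("affects only (Eye and Bone)")
#' @export
parse_manchester <- function(text, tbox = NULL) {
  toks <- tokenize_manchester(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$text <- text
  out <- parse_mn_expr(st, tbox)
  if (st$pos <= length(st$toks$value))
    parse_fail(st, sprintf("unexpected token '%s'", st$toks$value[st$pos]))
  out
}

MN_KEYWORDS <- c("and", "not", "only", "min", "max", "Thing", "Nothing")

tokenize_manchester <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  value <- character(); type <- character(); at <- integer()
  i <- 1L; n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      value <- c(value, ch); type <- c(type, "paren"); at <- c(at, i)
      i <- i + 1L; next
    }
    m <- regmatches(substr(text, i, n), regexpr("^[0-9]+", substr(text, i, n)))
    if (length(m) == 1L && nzchar(m)) {
      value <- c(value, m); type <- c(type, "int"); at <- c(at, i)
      i <- i + nchar(m); next
    }
    m <- regmatches(substr(text, i, n), regexpr("^:?[A-Za-z_][A-Za-z0-9_.:-]*", substr(text, i, n)))
    if (length(m) == 1L && nzchar(m)) {
      v <- sub("^:", "", m)
      value <- c(value, v)
      type <- c(type, if (v %in% MN_KEYWORDS) "kw" else "name")
      at <- c(at, i)
      i <- i + nchar(m); next
    }
    stop(sprintf("syntax error at position %d: unexpected character '%s'", i, ch),
         call. = FALSE)
  }
  list(value = value, type = type, at = at)
}

parse_fail <- function(st, msg) {
  pos <- if (st$pos <= length(st$toks$at)) st$toks$at[st$pos] else nchar(st$text) + 1L
  stop(sprintf("syntax error at position %d: %s", pos, msg), call. = FALSE)
}

peek_tok <- function(st) {
  if (st$pos > length(st$toks$value)) return(NULL)
  list(value = st$toks$value[st$pos], type = st$toks$type[st$pos])
}

take_tok <- function(st) {
  t <- peek_tok(st)
  if (is.null(t)) parse_fail(st, "unexpected end of input")
  st$pos <- st$pos + 1L
  t
}

check_class_name <- function(name, tbox) {
  if (!is.null(tbox) && !name %in% tbox_class_names(tbox))
    stop(sprintf("unknown name '%s'", name), call. = FALSE)
}

check_role_name <- function(name, tbox) {
  if (!is.null(tbox) && !name %in% tbox$roles)
    stop(sprintf("unknown name '%s'", name), call. = FALSE)
}

parse_mn_expr <- function(st, tbox) {
  parts <- list(parse_mn_primary(st, tbox))
  repeat {
    t <- peek_tok(st)
    if (is.null(t) || !(t$type == "kw" && t$value == "and")) break
    take_tok(st)
    parts <- c(parts, list(parse_mn_primary(st, tbox)))
  }
  aln_and(parts)
}

parse_mn_primary <- function(st, tbox) {
  t <- take_tok(st)
  if (t$type == "paren" && t$value == "(") {
    out <- parse_mn_expr(st, tbox)
    cl <- take_tok(st)
    if (!(cl$type == "paren" && cl$value == ")")) {
      st$pos <- st$pos - 1L
      parse_fail(st, "expected ')'")
    }
    return(out)
  }
  if (t$type == "kw") {
    if (t$value == "Thing") return(aln_top())
    if (t$value == "Nothing") return(aln_bottom())
    if (t$value == "not") {
      nm <- take_tok(st)
      if (nm$type != "name") { st$pos <- st$pos - 1L; parse_fail(st, "'not' must be followed by a concept name") }
      check_class_name(nm$value, tbox)
      return(aln_not(nm$value))
    }
    st$pos <- st$pos - 1L
    parse_fail(st, sprintf("unexpected keyword '%s'", t$value))
  }
  if (t$type != "name") { st$pos <- st$pos - 1L; parse_fail(st, sprintf("unexpected token '%s'", t$value)) }
  nxt <- peek_tok(st)
  if (!is.null(nxt) && nxt$type == "kw" && nxt$value %in% c("only", "min", "max")) {
    role <- t$value
    check_role_name(role, tbox)
    op <- take_tok(st)
    if (op$value == "only") {
      return(aln_all(role, parse_mn_primary(st, tbox)))
    }
    num <- take_tok(st)
    if (num$type != "int") { st$pos <- st$pos - 1L; parse_fail(st, sprintf("'%s' requires an integer", op$value)) }
    n <- as.integer(num$value)
    return(if (op$value == "min") aln_min(n, role) else aln_max(n, role))
  }
  check_class_name(t$value, tbox)
  aln_name(t$value)
}

#' Parse a functional-style class expression
#'
#' Accepts the `ObjectIntersectionOf` / `ObjectComplementOf` /
#' `ObjectAllValuesFrom` / `ObjectMinCardinality` / `ObjectMaxCardinality`
#' constructors plus `owl:Thing` and `owl:Nothing`; this is the same ALN
#' fragment as [parse_manchester()], in the OWL 2 functional-style
#' serialization.
#'
#' @inheritParams parse_manchester
#' @return An `aln_concept`.
#' @export
parse_functional <- function(text, tbox = NULL) {
  st <- new.env(parent = emptyenv())
  st$toks <- tokenize_functional(text); st$pos <- 1L; st$text <- text
  out <- parse_fn_expr(st, tbox)
  if (st$pos <= length(st$toks$value))
    parse_fail(st, sprintf("unexpected token '%s'", st$toks$value[st$pos]))
  out
}

tokenize_functional <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  value <- character(); type <- character(); at <- integer()
  i <- 1L; n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      value <- c(value, ch); type <- c(type, "paren"); at <- c(at, i); i <- i + 1L; next
    }
    rest <- substr(text, i, n)
    m <- regmatches(rest, regexpr("^[0-9]+", rest))
    if (length(m) == 1L && nzchar(m)) {
      value <- c(value, m); type <- c(type, "int"); at <- c(at, i); i <- i + nchar(m); next
    }
    m <- regmatches(rest, regexpr("^:?[A-Za-z_][A-Za-z0-9_.:-]*", rest))
    if (length(m) == 1L && nzchar(m)) {
      value <- c(value, sub("^:", "", m)); type <- c(type, "name"); at <- c(at, i)
      i <- i + nchar(m); next
    }
    stop(sprintf("syntax error at position %d: unexpected character '%s'", i, ch), call. = FALSE)
  }
  list(value = value, type = type, at = at)
}

expect_paren <- function(st, which) {
  t <- take_tok(st)
  if (!(t$type == "paren" && t$value == which)) {
    st$pos <- st$pos - 1L
    parse_fail(st, sprintf("expected '%s'", which))
  }
}

parse_fn_expr <- function(st, tbox) {
  t <- take_tok(st)
  if (t$type != "name") { st$pos <- st$pos - 1L; parse_fail(st, "expected a class expression") }
  if (t$value %in% c("owl:Thing", "Thing")) return(aln_top())
  if (t$value %in% c("owl:Nothing", "Nothing")) return(aln_bottom())
  switch(t$value,
    ObjectIntersectionOf = {
      expect_paren(st, "(")
      parts <- list()
      while (!is.null(pk <- peek_tok(st)) && !(pk$type == "paren" && pk$value == ")"))
        parts <- c(parts, list(parse_fn_expr(st, tbox)))
      expect_paren(st, ")")
      if (length(parts) < 2L)
        parse_fail(st, "ObjectIntersectionOf requires at least two operands")
      aln_and(parts)
    },
    ObjectComplementOf = {
      expect_paren(st, "(")
      inner <- parse_fn_expr(st, tbox)
      if (inner$kind != "name")
        parse_fail(st, "ALN negation applies to concept names only")
      expect_paren(st, ")")
      aln_not(inner$name)
    },
    ObjectAllValuesFrom = {
      expect_paren(st, "(")
      role <- take_tok(st)
      if (role$type != "name") { st$pos <- st$pos - 1L; parse_fail(st, "expected a role name") }
      check_role_name(role$value, tbox)
      filler <- parse_fn_expr(st, tbox)
      expect_paren(st, ")")
      aln_all(role$value, filler)
    },
    ObjectMinCardinality = ,
    ObjectMaxCardinality = {
      expect_paren(st, "(")
      num <- take_tok(st)
      if (num$type != "int") { st$pos <- st$pos - 1L; parse_fail(st, "expected a cardinality") }
      role <- take_tok(st)
      if (role$type != "name") { st$pos <- st$pos - 1L; parse_fail(st, "expected a role name") }
      check_role_name(role$value, tbox)
      expect_paren(st, ")")
      n <- as.integer(num$value)
      if (t$value == "ObjectMinCardinality") aln_min(n, role$value) else aln_max(n, role$value)
    },
    {
      # bare class name
      check_class_name(t$value, tbox)
      aln_name(t$value)
    }
  )
}

#' Parse a concept in a chosen syntax
#'
#' @param text Concept expression text.
#' @param syntax `"manchester"` or `"functional"`.
#' @param tbox Optional [tbox()] for name validation.
#' @return An `aln_concept`.
#' @export
parse_concept <- function(text, syntax = c("manchester", "functional"), tbox = NULL) {
  syntax <- match.arg(syntax)
  if (syntax == "manchester") parse_manchester(text, tbox) else parse_functional(text, tbox)
}

#' Serialize a concept in a chosen syntax
#'
#' @param x An `aln_concept`.
#' @param syntax `"manchester"` or `"functional"`.
#' @return A single string.
#' @export
serialize_concept <- function(x, syntax = c("manchester", "functional")) {
  syntax <- match.arg(syntax)
  if (syntax == "manchester") to_manchester(x) else to_functional(x)
}
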