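#' ALN concept expressions
#'
#' Constructors for concept expressions of the description logic ALN
#' (attributive language with unqualified number restrictions): concept
#' names, atomic negation, conjunction, universal role restrictions and
#' unqualified minimum/maximum cardinality restrictions, plus the top and
#' bottom concepts. Expressions are plain recursive lists of class
#' `"aln_concept"`; all reasoning operates on these trees.
#'
#' @param name Concept name (non-empty string).
#' @param role Role name (non-empty string).
#' @param n Non-negative integer bound.
#' @param filler An `aln_concept` used as the filler of a universal
#'   restriction.
#' @param ... For [aln_and()], two or more `aln_concept` arguments (or a
#'   single list of them).
#' @return An object of class `aln_concept`.
#' @examples
#' aln_and(aln_name("PDM"), aln_name("Anemia"))
#' aln_all("affects", aln_not("CardiovascularSystem"))
#' @name aln_concept
NULL

new_concept <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "aln_concept")
}

#' @rdname aln_concept
#' @export
aln_top <- function() new_concept("top")

#' @rdname aln_concept
#' @export
aln_bottom <- function() new_concept("bottom")

#' @rdname aln_concept
#' @export
aln_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  new_concept("name", name = name)
}

#' @rdname aln_concept
#' @export
aln_not <- function(name) {
  if (inherits(name, "aln_concept")) {
    if (name$kind != "name")
      stop("ALN only supports negation of concept names", call. = FALSE)
    name <- name$name
  }
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  new_concept("not", name = name)
}

#' @rdname aln_concept
#' @export
aln_and <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) && !inherits(args[[1L]], "aln_concept"))
    args <- args[[1L]]
  stopifnot(all(vapply(args, inherits, logical(1L), "aln_concept")))
  if (length(args) == 0L) return(aln_top())
  if (length(args) == 1L) return(args[[1L]])
  new_concept("and", args = args)
}

#' @rdname aln_concept
#' @export
aln_all <- function(role, filler) {
  stopifnot(is.character(role), length(role) == 1L, nzchar(role),
            inherits(filler, "aln_concept"))
  new_concept("all", role = role, filler = filler)
}

#' @rdname aln_concept
#' @export
aln_min <- function(n, role) {
  stopifnot(is.numeric(n), n >= 0, n == round(n),
            is.character(role), nzchar(role))
  new_concept("min", n = as.integer(n), role = role)
}

#' @rdname aln_concept
#' @export
aln_max <- function(n, role) {
  stopifnot(is.numeric(n), n >= 0, n == round(n),
            is.character(role), nzchar(role))
  new_concept("max", n = as.integer(n), role = role)
}

#' Syntactic conjunction of two concepts
#'
#' Returns the syntactic conjunction `C and D` without normalizing; top
#' operands are absorbed so that `conjoin(Thing, D)` is `D` itself.
#'
#' @param c,d Concept expressions.
#' @return An `aln_concept`.
#' @export
conjoin <- function(c, d) {
  stopifnot(inherits(c, "aln_concept"), inherits(d, "aln_concept"))
  if (c$kind == "top") return(d)
  if (d$kind == "top") return(c)
  cc <- if (c$kind == "and") c$args else list(c)
  dd <- if (d$kind == "and") d$args else list(d)
  aln_and(c(cc, dd))
}

# flat list of top-level conjuncts, top dropped
concept_conjuncts <- function(x) {
  if (x$kind == "and") {
    out <- list()
    for (a in x$args) out <- c(out, concept_conjuncts(a))
    out
  } else if (x$kind == "top") {
    list()
  } else {
    list(x)
  }
}

#' Serialize a concept to the Manchester subset
#'
#' Writes a concept expression with the keywords `and`, `not`, `only`,
#' `min`, `max`, `Thing`, `Nothing`. Complex fillers of `only` are
#' parenthesized; conjunct order is preserved as stored.
#'
#' @param x An `aln_concept`.
#' @return A single string.
#' @examples
#' to_manchester(aln_all("affects", aln_and(aln_name("Eye"), aln_name("Bone"))))
#' @export
to_manchester <- function(x) {
  stopifnot(inherits(x, "aln_concept"))
  switch(x$kind,
    top = "Thing",
    bottom = "Nothing",
    name = x$name,
    not = paste("not", x$name),
    min = paste(x$role, "min", x$n),
    max = paste(x$role, "max", x$n),
    all = {
      f <- to_manchester(x$filler)
      if (!x$filler$kind %in% c("name", "top", "bottom")) f <- paste0("(", f, ")")
      paste(x$role, "only", f)
    },
    and = paste(vapply(x$args, function(a) {
      s <- to_manchester(a)
      if (a$kind %in% c("and", "not", "min", "max")) s <- paste0("(", s, ")")
      if (a$kind == "all") s <- paste0("(", s, ")")
      s
    }, character(1L)), collapse = " and ")
  )
}

#' Serialize a concept to the OWL functional-style subset
#'
#' Writes `ObjectIntersectionOf`, `ObjectComplementOf`,
#' `ObjectAllValuesFrom`, `ObjectMinCardinality`, `ObjectMaxCardinality`,
#' `owl:Thing` and `owl:Nothing`.
#'
#' @param x An `aln_concept`.
#' @return A single string.
#' @export
to_functional <- function(x) {
  stopifnot(inherits(x, "aln_concept"))
  switch(x$kind,
    top = "owl:Thing",
    bottom = "owl:Nothing",
    name = x$name,
    not = paste0("ObjectComplementOf(", x$name, ")"),
    min = paste0("ObjectMinCardinality(", x$n, " ", x$role, ")"),
    max = paste0("ObjectMaxCardinality(", x$n, " ", x$role, ")"),
    all = paste0("ObjectAllValuesFrom(", x$role, " ", to_functional(x$filler), ")"),
    and = paste0("ObjectIntersectionOf(",
                 paste(vapply(x$args, to_functional, character(1L)), collapse = " "),
                 ")")
  )
}

#' @export
print.aln_concept <- function(x, ...) {
  cat("<ALN concept> ", to_manchester(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.aln_concept <- function(x, ...) to_manchester(x)

# structural equality up to stored order
concept_identical <- function(a, b) identical(unclass_deep(a), unclass_deep(b))

unclass_deep <- function(x) {
  x <- unclass(x)
  if (!is.null(x$args)) x$args <- lapply(x$args, unclass_deep)
  if (!is.null(x$filler)) x$filler <- unclass_deep(x$filler)
  x
}

# names and roles occurring in a concept (used by validation and the tests'
# model-enumeration helpers)
concept_signature <- function(x) {
  names <- character(); roles <- character()
  walk <- function(e) {
    switch(e$kind,
      name = names <<- union(names, e$name),
      not = names <<- union(names, e$name),
      min = roles <<- union(roles, e$role),
      max = roles <<- union(roles, e$role),
      all = { roles <<- union(roles, e$role); walk(e$filler) },
      and = for (a in e$args) walk(a),
      NULL)
  }
  walk(x)
  list(names = names, roles = roles)
}
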