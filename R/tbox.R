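#' Acyclic ALN terminologies
#'
#' A `tbox` holds the terminological axioms the reasoner works against:
#' full definitions (`EquivalentClasses`, `A` \eqn{\equiv} `C`), primitive
#' inclusions (`SubClassOf`, `A` \eqn{\sqsubseteq} `C`), pairwise class
#' disjointness and role declarations. The definition/inclusion graph must
#' be acyclic; this is validated on construction so that unfolding always
#' terminates.
#'
#' @param classes Character vector of declared class names.
#' @param roles Character vector of declared role names.
#' @param definitions Named list of `aln_concept` (one definition per name).
#' @param inclusions Named list of `aln_concept` (the conjunction of all
#'   `SubClassOf` right-hand sides for a name).
#' @param disjoint List of length-2 character vectors (unordered pairs).
#' @param iri Ontology IRI.
#' @return An object of class `tbox`.
#' @export
tbox <- function(classes = character(), roles = character(),
                 definitions = list(), inclusions = list(),
                 disjoint = list(), iri = "urn:shdss:ontology") {
  stopifnot(is.character(classes), is.character(roles), is.list(definitions),
            is.list(inclusions), is.list(disjoint))
  if (length(definitions) && is.null(names(definitions)))
    stop("definitions must be a named list", call. = FALSE)
  if (length(inclusions) && is.null(names(inclusions)))
    stop("inclusions must be a named list", call. = FALSE)
  dup <- intersect(names(definitions), names(inclusions))
  if (length(dup))
    stop(sprintf("names cannot have both a definition and an inclusion: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  tb <- structure(list(classes = unique(classes), roles = unique(roles),
                       definitions = definitions, inclusions = inclusions,
                       disjoint = disjoint, iri = iri),
                  class = "tbox")
  check_acyclic(tb)
  tb
}

tbox_class_names <- function(tb) {
  unique(c(tb$classes, names(tb$definitions), names(tb$inclusions),
           unlist(tb$disjoint, use.names = FALSE)))
}

#' @export
print.tbox <- function(x, ...) {
  cat("<tbox> ", x$iri, "\n", sep = "")
  cat("  classes:     ", length(tbox_class_names(x)), "\n", sep = "")
  cat("  roles:       ", length(x$roles), "\n", sep = "")
  cat("  definitions: ", length(x$definitions), "\n", sep = "")
  cat("  inclusions:  ", length(x$inclusions), "\n", sep = "")
  cat("  disjoint:    ", length(x$disjoint), " pair(s)\n", sep = "")
  invisible(x)
}

# depth-first cycle check over the definition/inclusion graph
check_acyclic <- function(tb) {
  rhs <- c(tb$definitions, tb$inclusions)
  color <- new.env(parent = emptyenv())  # 1 = visiting, 2 = done
  visit <- function(a, path) {
    st <- get0(a, envir = color, ifnotfound = 0L)
    if (st == 2L) return(invisible())
    if (st == 1L)
      stop(sprintf("terminology error: cyclic definition through '%s' (%s)",
                   a, paste(c(path, a), collapse = " -> ")), call. = FALSE)
    assign(a, 1L, envir = color)
    if (!is.null(rhs[[a]]))
      for (dep in concept_signature(rhs[[a]])$names) visit(dep, c(path, a))
    assign(a, 2L, envir = color)
  }
  for (a in names(rhs)) visit(a, character())
  invisible(tb)
}

disjoint_partners <- function(tb, name) {
  out <- character()
  for (p in tb$disjoint)
    if (name %in% p) out <- c(out, setdiff(p, name))
  unique(out)
}

#' Unfold a concept with respect to an acyclic terminology
#'
#' Recursively replaces defined names by their definitions, conjoins the
#' right-hand side of every inclusion onto occurrences of the included
#' name (the name itself is retained as a human-readable marker), and
#' compiles class disjointness into atomic negation: each occurrence of
#' `A` gains `not B` for every disjoint pair `{A, B}`. The result mentions
#' primitive names only, so the structural algorithms can ignore the
#' terminology afterwards.
#'
#' @param x An `aln_concept`.
#' @param tbox A [tbox()].
#' @return An `aln_concept` free of defined names.
#' @export
unfold <- function(x, tbox) {
  stopifnot(inherits(x, "aln_concept"), inherits(tbox, "tbox"))
  unfold_rec(x, tbox, character())
}

unfold_rec <- function(x, tb, visiting) {
  switch(x$kind,
    name = {
      a <- x$name
      if (a %in% visiting)
        stop(sprintf("terminology error: cyclic definition through '%s'", a), call. = FALSE)
      parts <- list()
      if (!is.null(tb$definitions[[a]])) {
        parts <- concept_conjuncts(unfold_rec(tb$definitions[[a]], tb, c(visiting, a)))
      } else {
        parts <- list(aln_name(a))
        if (!is.null(tb$inclusions[[a]]))
          parts <- c(parts, concept_conjuncts(unfold_rec(tb$inclusions[[a]], tb, c(visiting, a))))
      }
      for (b in disjoint_partners(tb, a)) parts <- c(parts, list(aln_not(b)))
      aln_and(parts)
    },
    and = aln_and(lapply(x$args, unfold_rec, tb = tb, visiting = visiting)),
    all = aln_all(x$role, unfold_rec(x$filler, tb, visiting)),
    x  # top, bottom, not, min, max are already primitive
  )
}

#' Read a terminology from the OWL functional-style subset
#'
#' Accepts documents made of `Prefix(...)` and an `Ontology(<iri> ...)`
#' wrapper containing `Declaration(Class(...))`,
#' `Declaration(ObjectProperty(...))`, `SubClassOf(A C)`,
#' `EquivalentClasses(A C)` and `DisjointClasses(A B ...)` axioms, with
#' class expressions in the ALN fragment of [parse_functional()]. Multiple
#' `SubClassOf` axioms for one name are conjoined. Acyclicity is validated
#' at load time.
#'
#' @param source A file path or a character vector of lines.
#' @return A [tbox()].
#' @export
load_ontology <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source)) readLines(source, warn = FALSE) else source
  text <- paste(lines, collapse = "\n")
  iri <- "urn:shdss:ontology"
  m <- regmatches(text, regexpr("Ontology\\(\\s*<[^>]*>", text))
  if (length(m) == 1L && nzchar(m))
    iri <- sub("^Ontology\\(\\s*<([^>]*)>$", "\\1", m)
  classes <- character(); roles <- character()
  definitions <- list(); inclusions <- list(); disjoint <- list()

  for (ax in extract_axioms(text)) {
    head <- ax$head; body <- ax$body
    if (head == "Prefix" || head == "Ontology") next
    if (head == "Declaration") {
      inner <- extract_axioms(body)
      if (length(inner) != 1L)
        stop(sprintf("line %d: malformed Declaration", ax$line), call. = FALSE)
      nm <- sub("^:", "", trimws(inner[[1L]]$body))
      if (inner[[1L]]$head == "Class") classes <- c(classes, nm)
      else if (inner[[1L]]$head == "ObjectProperty") roles <- c(roles, nm)
      else stop(sprintf("line %d: unsupported declaration '%s'", ax$line, inner[[1L]]$head), call. = FALSE)
      next
    }
    if (head == "SubClassOf" || head == "EquivalentClasses") {
      sp <- split_functional_args(body, ax$line)
      if (length(sp) != 2L)
        stop(sprintf("line %d: %s requires exactly two operands", ax$line, head), call. = FALSE)
      lhs <- sub("^:", "", trimws(sp[[1L]]))
      if (!grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", lhs))
        stop(sprintf("line %d: left-hand side of %s must be a class name", ax$line, head), call. = FALSE)
      rhs <- parse_functional(sp[[2L]])
      if (head == "SubClassOf") {
        inclusions[[lhs]] <- if (is.null(inclusions[[lhs]])) rhs else conjoin(inclusions[[lhs]], rhs)
      } else {
        if (!is.null(definitions[[lhs]]))
          stop(sprintf("line %d: '%s' already has a definition", ax$line, lhs), call. = FALSE)
        definitions[[lhs]] <- rhs
      }
      next
    }
    if (head == "DisjointClasses") {
      nms <- vapply(split_functional_args(body, ax$line),
                    function(s) sub("^:", "", trimws(s)), character(1L))
      if (length(nms) < 2L)
        stop(sprintf("line %d: DisjointClasses requires at least two names", ax$line), call. = FALSE)
      for (i in seq_len(length(nms) - 1L))
        for (j in (i + 1L):length(nms))
          disjoint <- c(disjoint, list(sort(c(nms[i], nms[j]))))
      next
    }
    stop(sprintf("line %d: unsupported axiom '%s'", ax$line, head), call. = FALSE)
  }
  tbox(classes = classes, roles = roles, definitions = definitions,
       inclusions = inclusions, disjoint = disjoint, iri = iri)
}

# top-level Head( ... ) chunks with balanced parentheses; the Ontology(...)
# wrapper is transparent (its inner axioms are lifted to the top level)
extract_axioms <- function(text) {
  out <- list()
  n <- nchar(text); i <- 1L; line <- 1L
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "\n") line <- line + 1L
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch == ")") { i <- i + 1L; next }  # closing of a transparent wrapper
    rest <- substr(text, i, n)
    m <- regmatches(rest, regexpr("^[A-Za-z][A-Za-z]*", rest))
    if (length(m) != 1L || !nzchar(m))
      stop(sprintf("line %d: syntax error near '%s'", line,
                   substr(text, i, min(n, i + 20L))), call. = FALSE)
    head <- m
    j <- i + nchar(m)
    while (j <= n && grepl("^[[:space:]]$", substr(text, j, j))) j <- j + 1L
    if (j > n || substr(text, j, j) != "(")
      stop(sprintf("line %d: expected '(' after '%s'", line, head), call. = FALSE)
    if (head == "Ontology") {
      # consume "Ontology(" and optional <iri>, then continue at top level
      j <- j + 1L
      while (j <= n && grepl("^[[:space:]]$", substr(text, j, j))) j <- j + 1L
      if (j <= n && substr(text, j, j) == "<") {
        k <- regexpr(">", substr(text, j, n), fixed = TRUE)
        if (k < 0) stop(sprintf("line %d: unterminated IRI", line), call. = FALSE)
        j <- j + k
      }
      i <- j
      next
    }
    depth <- 0L; k <- j
    while (k <= n) {
      ck <- substr(text, k, k)
      if (ck == "\n") line <- line + 1L
      if (ck == "(") depth <- depth + 1L
      if (ck == ")") { depth <- depth - 1L; if (depth == 0L) break }
      k <- k + 1L
    }
    if (depth != 0L)
      stop(sprintf("line %d: unbalanced parentheses in '%s'", line, head), call. = FALSE)
    out <- c(out, list(list(head = head, body = substr(text, j + 1L, k - 1L), line = line)))
    i <- k + 1L
  }
  out
}

# split a functional axiom body into top-level operands
split_functional_args <- function(body, line = NA_integer_) {
  n <- nchar(body); parts <- character(); depth <- 0L; start <- NA_integer_
  i <- 1L
  while (i <= n) {
    ch <- substr(body, i, i)
    if (grepl("^[[:space:]]$", ch) && depth == 0L) {
      if (!is.na(start)) { parts <- c(parts, substr(body, start, i - 1L)); start <- NA_integer_ }
    } else {
      if (is.na(start)) start <- i
      if (ch == "(") depth <- depth + 1L
      if (ch == ")") depth <- depth - 1L
    }
    i <- i + 1L
  }
  if (!is.na(start)) parts <- c(parts, substr(body, start, n))
  as.list(parts)
}

#' Serialize a terminology to the functional-style subset
#'
#' Deterministic output (declarations first, then axioms in sorted name
#' order) that [load_ontology()] reads back unchanged.
#'
#' @param tb A [tbox()].
#' @return Character vector of lines.
#' @export
serialize_ontology <- function(tb) {
  stopifnot(inherits(tb, "tbox"))
  out <- c(sprintf("Ontology(<%s>", tb$iri))
  for (cl in sort(tbox_class_names(tb)))
    out <- c(out, sprintf("Declaration(Class(%s))", cl))
  for (r in sort(tb$roles))
    out <- c(out, sprintf("Declaration(ObjectProperty(%s))", r))
  for (a in sort(names(tb$definitions)))
    out <- c(out, sprintf("EquivalentClasses(%s %s)", a, to_functional(tb$definitions[[a]])))
  for (a in sort(names(tb$inclusions)))
    out <- c(out, sprintf("SubClassOf(%s %s)", a, to_functional(tb$inclusions[[a]])))
  pairs <- unique(vapply(tb$disjoint, function(p) paste(sort(p), collapse = " "), character(1L)))
  for (p in sort(pairs))
    out <- c(out, sprintf("DisjointClasses(%s)", p))
  c(out, ")")
}
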