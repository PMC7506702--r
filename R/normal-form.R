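#' ALN conjunctive normal form
#'
#' [normalize()] rewrites a concept into the canonical form the structural
#' algorithms operate on: conjunctions are flattened and deduplicated,
#' universal restrictions over the same role are merged
#' (\eqn{\forall R.C_1 \sqcap \forall R.C_2 \to \forall R.(C_1 \sqcap C_2)}),
#' minimum bounds keep the maximum and maximum bounds the minimum, and the
#' clash rules are applied: a name occurring both positively and negated,
#' `min > max` on a role, or a minimum cardinality of at least one on a
#' role whose filler normalizes to bottom. Insertion order is preserved so
#' serialized output is reproducible.
#'
#' A normal form with an unsatisfiable filler but no matching minimum
#' cardinality is *not* globally bottom (`all R Nothing` is satisfiable by
#' having no `R` successor); such filler-level clashes are what the
#' matchmaking layer reports as contraindications and interactions — see
#' [has_deep_clash()].
#'
#' @param x An `aln_concept` (normally already unfolded; [normalize()] does
#'   not consult a terminology).
#' @return An object of class `aln_nf` with fields `bottom`, `pos`, `neg`,
#'   `minc`, `maxc` (named integer vectors) and `univ` (named list of
#'   `aln_nf` fillers).
#' @export
normalize <- function(x) {
  stopifnot(inherits(x, "aln_concept"))
  nf <- list(bottom = FALSE, pos = character(), neg = character(),
             minc = integer(), maxc = integer(), univ = list())
  fillers <- list()  # role -> list of filler concepts, merged at the end
  for (a in concept_conjuncts(x)) {
    switch(a$kind,
      bottom = { nf$bottom <- TRUE },
      name = nf$pos <- union(nf$pos, a$name),
      not = nf$neg <- union(nf$neg, a$name),
      min = if (a$n > 0L) {
        cur <- nf$minc[a$role]
        nf$minc[a$role] <- if (is.na(cur)) a$n else max(cur, a$n)
      },
      max = {
        cur <- nf$maxc[a$role]
        nf$maxc[a$role] <- if (is.na(cur)) a$n else min(cur, a$n)
      },
      all = fillers[[a$role]] <- c(fillers[[a$role]], list(a$filler)),
      stop("unexpected conjunct kind: ", a$kind)
    )
  }
  for (r in names(fillers))
    nf$univ[[r]] <- normalize(aln_and(fillers[[r]]))
  if (length(intersect(nf$pos, nf$neg))) nf$bottom <- TRUE
  for (r in names(nf$minc)) {
    mx <- effective_max(nf, r)
    if (!is.na(mx) && nf$minc[r] > mx) nf$bottom <- TRUE
  }
  if (nf$bottom)
    nf <- list(bottom = TRUE, pos = character(), neg = character(),
               minc = integer(), maxc = integer(), univ = list())
  structure(nf, class = "aln_nf")
}

# entailed upper bound on R-successors: an explicit max restriction, or 0
# when the merged filler is unsatisfiable
effective_max <- function(nf, role) {
  mx <- nf$maxc[role]
  u <- nf$univ[[role]]
  if (!is.null(u) && u$bottom) mx <- if (is.na(mx)) 0L else min(mx, 0L)
  mx  # NA means unbounded
}

nf_is_top <- function(nf) {
  !nf$bottom && !length(nf$pos) && !length(nf$neg) &&
    !length(nf$minc) && !length(nf$maxc) && !length(nf$univ)
}

#' Rebuild a concept expression from a normal form
#'
#' Conjunct order is pos names, negated names, minimum then maximum
#' restrictions, then universal restrictions, each in stored (insertion)
#' order.
#'
#' @param nf An `aln_nf`.
#' @return An `aln_concept`.
#' @export
nf_to_concept <- function(nf) {
  stopifnot(inherits(nf, "aln_nf"))
  if (nf$bottom) return(aln_bottom())
  parts <- list()
  for (a in nf$pos) parts <- c(parts, list(aln_name(a)))
  for (a in nf$neg) parts <- c(parts, list(aln_not(a)))
  for (r in names(nf$minc)) parts <- c(parts, list(aln_min(nf$minc[[r]], r)))
  for (r in names(nf$maxc)) parts <- c(parts, list(aln_max(nf$maxc[[r]], r)))
  for (r in names(nf$univ)) parts <- c(parts, list(aln_all(r, nf_to_concept(nf$univ[[r]]))))
  aln_and(parts)
}

#' @export
print.aln_nf <- function(x, ...) {
  cat("<ALN normal form> ", to_manchester(nf_to_concept(x)), "\n", sep = "")
  invisible(x)
}

#' Satisfiability of a normalized concept
#'
#' A concept is unsatisfiable exactly when full recursive normalization
#' flags bottom: a direct clash, incompatible cardinality bounds, or an
#' unsatisfiable filler forced non-empty by a minimum cardinality. An
#' unsatisfiable filler alone does not make the concept unsatisfiable
#' (there may simply be no successor for that role).
#'
#' @param x An `aln_concept` or `aln_nf`.
#' @param tbox Optional [tbox()]; when supplied, `x` is unfolded first.
#' @return Logical.
#' @export
is_satisfiable <- function(x, tbox = NULL) {
  !as_nf(x, tbox)$bottom
}

as_nf <- function(x, tbox = NULL) {
  if (inherits(x, "aln_nf")) return(x)
  stopifnot(inherits(x, "aln_concept"))
  if (!is.null(tbox)) x <- unfold(x, tbox)
  normalize(x)
}

#' Clash detection at any filler depth
#'
#' `TRUE` when the normal form is bottom at the top level *or* any nested
#' universal-restriction filler is bottom. This is the compatibility test
#' the matchmaking layer uses: a treatment whose conjunction with the
#' patient profile clashes inside a role filler (for example under an
#' interaction role such as `reduces`) is flagged even though the
#' conjunction may remain ALN-satisfiable for lack of a minimum
#' cardinality on that role.
#'
#' @inheritParams is_satisfiable
#' @return Logical.
#' @export
has_deep_clash <- function(x, tbox = NULL) {
  nf <- as_nf(x, tbox)
  deep_clash_nf(nf)
}

deep_clash_nf <- function(nf) {
  if (nf$bottom) return(TRUE)
  for (u in nf$univ) if (deep_clash_nf(u)) return(TRUE)
  FALSE
}

#' Structural subsumption
#'
#' Decides `C` \eqn{\sqsupseteq} `D` by structural comparison of the
#' unfolded normal forms: every (negated) name of `C` must occur in `D`,
#' every minimum bound of `C` must be at most `D`'s, every maximum bound
#' at least `D`'s, and each universal filler of `C` must subsume `D`'s
#' filler for that role (a missing filler in `D` behaves as Thing; a role
#' `D` provably has no successors for satisfies any universal
#' restriction).
#'
#' @param c,d Concept expressions (`aln_concept` or `aln_nf`).
#' @param tbox Optional [tbox()] used to unfold both sides.
#' @return Logical: `TRUE` iff `C` subsumes `D`.
#' @export
subsumes <- function(c, d, tbox = NULL) {
  subsumes_nf(as_nf(c, tbox), as_nf(d, tbox))
}

subsumes_nf <- function(cnf, dnf) {
  if (dnf$bottom) return(TRUE)
  if (cnf$bottom) return(FALSE)
  if (!all(cnf$pos %in% dnf$pos)) return(FALSE)
  if (!all(cnf$neg %in% dnf$neg)) return(FALSE)
  for (r in names(cnf$minc)) {
    dmin <- dnf$minc[r]
    if (is.na(dmin) || dmin < cnf$minc[r]) return(FALSE)
  }
  for (r in names(cnf$maxc)) {
    dmax <- effective_max(dnf, r)
    if (is.na(dmax) || dmax > cnf$maxc[r]) return(FALSE)
  }
  for (r in names(cnf$univ)) {
    dmax <- effective_max(dnf, r)
    if (!is.na(dmax) && dmax == 0L) next  # D has no R-successors
    dfill <- dnf$univ[[r]]
    if (is.null(dfill)) dfill <- normalize(aln_top())
    if (!subsumes_nf(cnf$univ[[r]], dfill)) return(FALSE)
  }
  TRUE
}

#' Concept equivalence
#'
#' Mutual subsumption with respect to an optional terminology.
#'
#' @inheritParams subsumes
#' @return Logical.
#' @export
equivalent_concepts <- function(c, d, tbox = NULL) {
  cnf <- as_nf(c, tbox); dnf <- as_nf(d, tbox)
  subsumes_nf(cnf, dnf) && subsumes_nf(dnf, cnf)
}
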