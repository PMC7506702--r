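#' Penalty score of a concept
#'
#' Semantic-distance weight used by the ranking layer, computed on the
#' unfolded normal form: each concept name or negated name counts one,
#' each number restriction counts one, and a universal restriction
#' contributes the penalty of its filler. `Thing` scores zero, so a full
#' match carries no penalty; the rule is additive over conjunct-disjoint
#' concepts and order-independent, which is all the utility function
#' requires.
#'
#' @param x An `aln_concept`.
#' @param tbox Optional [tbox()]; when given, `x` is unfolded first.
#' @return Non-negative number (`Inf` for an unsatisfiable concept).
#' @export
penalty <- function(x, tbox = NULL) {
  penalty_nf(as_nf(x, tbox))
}

penalty_nf <- function(nf) {
  if (nf$bottom) return(Inf)
  p <- as.numeric(length(nf$pos) + length(nf$neg) + length(nf$minc) + length(nf$maxc))
  for (u in nf$univ) p <- p + penalty_nf(u)
  p
}

# ---- surface conjunct handling ------------------------------------------
#
# Contraction and abduction report their results over the *surface*
# conjuncts of the treatment description (what the annotation actually
# says), while clash and entailment are decided on unfolded forms. This
# keeps Give-up/Keep/Hypothesis human-readable: unfolding injects taxonomy
# markers (e.g. a body-structure superclass on every anatomical name) that
# a practitioner-facing explanation should not display.

# ordered list of single-conjunct concepts from a surface normal form
nf_sequence <- function(nf) {
  parts <- list()
  for (a in nf$pos) parts <- c(parts, list(aln_name(a)))
  for (a in nf$neg) parts <- c(parts, list(aln_not(a)))
  for (r in names(nf$minc)) parts <- c(parts, list(aln_min(nf$minc[[r]], r)))
  for (r in names(nf$maxc)) parts <- c(parts, list(aln_max(nf$maxc[[r]], r)))
  for (r in names(nf$univ)) parts <- c(parts, list(aln_all(r, nf_to_concept(nf$univ[[r]]))))
  parts
}

# does `atom` (a surface conjunct), once unfolded, clash with the already
# unfolded context `ctx` (aln_nf) at any filler depth?
atom_clashes <- function(atom, ctx, tbox) {
  u <- normalize(conjoin(unfold(atom, tbox), nf_to_concept(ctx)))
  deep_clash_nf(u)
}

#' Concept Contraction
#'
#' Splits an incompatible treatment description `D` into the pair
#' \eqn{\langle G, K\rangle}: `G` ("give up") collects the conjuncts of
#' `D` that clash with the profile `P`, `K` ("keep") the rest, so that
#' `K` is compatible with `P` and `G and K` is equivalent to `D`. For a
#' role restricted universally by both sides the algorithm recurses into
#' the fillers and splits them, giving up as little as possible: no
#' conjunct of `G` is individually compatible with `P`. Give-up conjuncts
#' are ordered by the position of the conflicting constraint in the
#' profile, which makes reports deterministic.
#'
#' @param d Treatment description (`aln_concept`).
#' @param p Profile to contract against (`aln_concept`).
#' @param tbox A [tbox()].
#' @return A list of class `concept_contraction` with elements `give_up`,
#'   `keep` (both `aln_concept`) and `penalty_cc` (penalty of `give_up`).
#' @export
contract <- function(d, p, tbox) {
  stopifnot(inherits(d, "aln_concept"), inherits(p, "aln_concept"),
            inherits(tbox, "tbox"))
  pnf <- normalize(unfold(p, tbox))
  if (deep_clash_nf(pnf))
    stop("profile is itself inconsistent; cannot contract against it", call. = FALSE)
  res <- contract_nf(normalize(d), pnf, tbox)
  g <- aln_and(res$g); k <- aln_and(res$k)
  structure(list(give_up = g, keep = k, penalty_cc = penalty(g, tbox)),
            class = "concept_contraction")
}

# returns list(g = list of concepts ordered by clash-partner position in
# the profile, k = list of concepts in description order)
contract_nf <- function(dnf, pnf, tbox) {
  g <- list(); g_rank <- numeric(); k <- list()
  pseq <- nf_sequence(pnf)
  partner_rank <- function(atom) {
    for (i in seq_along(pseq)) {
      ctx <- normalize(pseq[[i]])
      if (atom_clashes(atom, ctx, tbox)) return(i)
    }
    Inf  # clash only against a combination of profile constraints
  }
  for (atom in nf_sequence(dnf)) {
    if (atom$kind == "all" && !is.null(pnf$univ[[atom$role]])) {
      sub <- contract_nf(normalize(atom$filler), pnf$univ[[atom$role]], tbox)
      if (length(sub$g)) {
        g <- c(g, list(aln_all(atom$role, aln_and(sub$g))))
        n_scalar <- length(pnf$pos) + length(pnf$neg) +
          length(pnf$minc) + length(pnf$maxc)
        g_rank <- c(g_rank, n_scalar + match(atom$role, names(pnf$univ)))
      }
      if (length(sub$k))
        k <- c(k, list(aln_all(atom$role, aln_and(sub$k))))
      next
    }
    if (atom_clashes(atom, pnf, tbox)) {
      g <- c(g, list(atom)); g_rank <- c(g_rank, partner_rank(atom))
    } else {
      k <- c(k, list(atom))
    }
  }
  if (length(g)) g <- g[order(g_rank, seq_along(g))]
  list(g = g, k = k)
}

#' Concept Abduction
#'
#' Computes the hypothesis `H`: what must be added to the profile `P` for
#' it to be subsumed by the (possibly contracted) description `D`. `H` is
#' the structural difference — the surface conjuncts of `D` not entailed
#' by `P`, recursing into universal fillers per role — and is minimal:
#' dropping any conjunct of `H` breaks `subsumes(D, P and H)`. A full
#' match leaves `H = Thing` with penalty zero.
#'
#' @param p Profile (`aln_concept`).
#' @param d Description to reach (`aln_concept`); pass the `keep` part of
#'   a [contract()] result when the original description clashes with `p`.
#' @param tbox A [tbox()].
#' @return A list of class `concept_abduction` with elements `hypothesis`
#'   (`aln_concept`) and `penalty_ca`.
#' @export
abduce <- function(p, d, tbox) {
  stopifnot(inherits(p, "aln_concept"), inherits(d, "aln_concept"),
            inherits(tbox, "tbox"))
  if (has_deep_clash(conjoin(p, d), tbox))
    stop("profile and description are incompatible; run contract() first",
         call. = FALSE)
  pnf <- normalize(unfold(p, tbox))
  h <- abduce_nf(normalize(d), pnf, tbox)
  h <- aln_and(h)
  structure(list(hypothesis = h, penalty_ca = penalty(h, tbox)),
            class = "concept_abduction")
}

abduce_nf <- function(dnf, pnf, tbox) {
  h <- list()
  for (atom in nf_sequence(dnf)) {
    if (atom$kind == "all") {
      r <- atom$role
      # redundant when the description itself forbids r-successors: the
      # max-cardinality conjunct already carries the requirement
      dmax <- dnf$maxc[r]
      if (!is.na(dmax) && dmax == 0L) next
      emax <- effective_max(pnf, r)
      if (!is.na(emax) && emax == 0L) next  # profile has no successors for r
      pfill <- pnf$univ[[r]]
      if (!is.null(pfill)) {
        sub <- abduce_nf(normalize(atom$filler), pfill, tbox)
        if (length(sub)) h <- c(h, list(aln_all(r, aln_and(sub))))
        next
      }
    }
    if (!subsumes_nf(normalize(unfold(atom, tbox)), pnf))
      h <- c(h, list(atom))
  }
  h
}

#' Match a treatment description against a profile
#'
#' The combined matchmaking classification. When the conjunction of
#' description and profile is clash-free at every filler depth, the
#' contraction is trivial and abduction measures what the profile lacks:
#' a *full* match if nothing (penalty 0), a *potential* match otherwise.
#' When they clash, [contract()] extracts the conflicting part first and
#' abduction runs against the kept part: a *partial* match.
#'
#' @param d Treatment description (`aln_concept`).
#' @param p Profile (`aln_concept`).
#' @param tbox A [tbox()].
#' @return A list of class `shdss_match` with elements `type` (one of
#'   `"full"`, `"potential"`, `"partial"`), `contraction` and `abduction`.
#' @export
match_profiles <- function(d, p, tbox) {
  stopifnot(inherits(d, "aln_concept"), inherits(p, "aln_concept"),
            inherits(tbox, "tbox"))
  compatible <- !has_deep_clash(conjoin(d, p), tbox)
  if (compatible) {
    ct <- structure(list(give_up = aln_top(), keep = d, penalty_cc = 0),
                    class = "concept_contraction")
    ab <- abduce(p, d, tbox)
    type <- if (ab$penalty_ca == 0) "full" else "potential"
  } else {
    ct <- contract(d, p, tbox)
    ab <- abduce(p, ct$keep, tbox)
    type <- "partial"
  }
  structure(list(type = type, contraction = ct, abduction = ab),
            class = "shdss_match")
}

#' @export
print.concept_contraction <- function(x, ...) {
  cat("Concept Contraction (penaltyCC = ", format(x$penalty_cc), ")\n",
      "  Give up: ", to_manchester(x$give_up), "\n",
      "  Keep:    ", to_manchester(x$keep), "\n", sep = "")
  invisible(x)
}

#' @export
print.concept_abduction <- function(x, ...) {
  cat("Concept Abduction (penaltyCA = ", format(x$penalty_ca), ")\n",
      "  Hypothesis: ", to_manchester(x$hypothesis), "\n", sep = "")
  invisible(x)
}

#' @export
print.shdss_match <- function(x, ...) {
  cat("<match> type = ", x$type,
      ", penaltyCC = ", format(x$contraction$penalty_cc),
      ", penaltyCA = ", format(x$abduction$penalty_ca), "\n", sep = "")
  if (x$type == "partial") {
    cat("  Give up: ", to_manchester(x$contraction$give_up), "\n", sep = "")
    cat("  Keep:    ", to_manchester(x$contraction$keep), "\n", sep = "")
  }
  if (x$abduction$penalty_ca > 0)
    cat("  Hypothesis: ", to_manchester(x$abduction$hypothesis), "\n", sep = "")
  invisible(x)
}
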