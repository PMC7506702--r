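# Brute-force model-enumeration oracle for ALN satisfiability and
# subsumption, independent of the structural reasoner: it enumerates every
# interpretation over the concept's own signature for domain sizes 1..3 and
# evaluates concepts semantically. The concept families compared against it
# are generated so that small models are complete (number bounds <= 2 at
# the top level, flat universal fillers): a satisfying/counter model then
# needs at most 1 + max-bound elements.

oracle_signature <- function(...) {
  sigs <- lapply(list(...), shdss:::concept_signature)
  list(names = unique(unlist(lapply(sigs, `[[`, "names"))),
       roles = unique(unlist(lapply(sigs, `[[`, "roles"))))
}

# evaluate a concept in an interpretation; returns logical over 1:d
oracle_eval <- function(x, ext, succ, d) {
  switch(x$kind,
    top = rep(TRUE, d),
    bottom = rep(FALSE, d),
    name = if (is.null(ext[[x$name]])) rep(FALSE, d) else ext[[x$name]],
    not = if (is.null(ext[[x$name]])) rep(TRUE, d) else !ext[[x$name]],
    and = Reduce(`&`, lapply(x$args, oracle_eval, ext = ext, succ = succ, d = d)),
    all = {
      fill <- oracle_eval(x$filler, ext, succ, d)
      s <- succ[[x$role]]
      vapply(seq_len(d), function(el) all(fill[s[[el]]]), logical(1L))
    },
    min = {
      s <- succ[[x$role]]
      vapply(seq_len(d), function(el) length(s[[el]]) >= x$n, logical(1L))
    },
    max = {
      s <- succ[[x$role]]
      vapply(seq_len(d), function(el) length(s[[el]]) <= x$n, logical(1L))
    },
    stop("unknown kind"))
}

# visit all interpretations over (names, roles, domain size d); fn returns
# TRUE to stop early, in which case oracle_scan returns TRUE
oracle_scan <- function(names, roles, d, fn) {
  nb <- length(names) * d
  rb <- length(roles) * d * d
  if (nb + rb > 16L) return(NA)  # caller skips domains this large
  for (code in 0:(2^(nb + rb) - 1)) {
    bits <- as.logical(bitwAnd(bitwShiftR(code, 0:(nb + rb - 1L)), 1L))
    ext <- list(); k <- 0L
    for (nm in names) { ext[[nm]] <- bits[k + seq_len(d)]; k <- k + d }
    succ <- list()
    for (r in roles) {
      per <- vector("list", d)
      for (el in seq_len(d)) {
        per[[el]] <- which(bits[k + seq_len(d)])
        k <- k + d
      }
      succ[[r]] <- per
    }
    if (isTRUE(fn(ext, succ, d))) return(TRUE)
  }
  FALSE
}

oracle_satisfiable <- function(x, max_domain = 2L) {
  sig <- oracle_signature(x)
  for (d in seq_len(max_domain)) {
    found <- oracle_scan(sig$names, sig$roles, d, function(ext, succ, d)
      any(oracle_eval(x, ext, succ, d)))
    if (isTRUE(found)) return(TRUE)
  }
  FALSE
}

# C subsumes D iff no interpretation holds an element in D but not in C
oracle_subsumes <- function(c, d, max_domain = 2L) {
  sig <- oracle_signature(c, d)
  for (dom in seq_len(max_domain)) {
    counter <- oracle_scan(sig$names, sig$roles, dom, function(ext, succ, dd)
      any(oracle_eval(d, ext, succ, dd) & !oracle_eval(c, ext, succ, dd)))
    if (isTRUE(counter)) return(FALSE)
  }
  TRUE
}

# systematic atom family over a 3-name/2-role signature (depth <= 2): the
# building blocks whose pairwise conjunctions the acceptance suite checks
oracle_atoms <- function() {
  c(list(aln_name("A"), aln_name("B"), aln_name("C"),
         aln_not("A"), aln_not("B"),
         aln_min(1L, "R"), aln_min(2L, "R"), aln_max(0L, "R"), aln_max(1L, "R"),
         aln_min(1L, "S"), aln_max(0L, "S")),
    list(aln_all("R", aln_name("A")),
         aln_all("R", aln_not("A")),
         aln_all("R", aln_and(aln_name("A"), aln_not("B"))),
         aln_all("R", aln_bottom()),
         aln_all("S", aln_name("B")),
         aln_all("R", aln_all("S", aln_name("C")))))
}
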