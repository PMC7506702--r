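# Random concept generators.
#
# gen_flat_concept() draws from the fragment the model-enumeration oracle
# is complete for with domain sizes 1-2: conjunctions of up to three atoms
# over a 3-name/2-role signature, number bounds <= 1, and flat universal
# fillers (conjunctions of literals). gen_tbox_concept() draws richer
# concepts (bounds <= 2, nesting depth <= 2) over the demo-terminology
# vocabulary for the matchmaking contract properties.

gen_flat_filler <- function() {
  lits <- list(aln_name("A"), aln_name("B"), aln_name("C"),
               aln_not("A"), aln_not("B"))
  aln_and(sample(lits, sample(1:2, 1L)))
}

gen_flat_atom <- function() {
  roll <- runif(1)
  if (roll < 0.45) {
    nm <- sample(c("A", "B", "C"), 1L)
    if (runif(1) < 0.4) aln_not(nm) else aln_name(nm)
  } else if (roll < 0.65) {
    aln_min(1L, sample(c("R", "S"), 1L))
  } else if (roll < 0.8) {
    aln_max(sample(0:1, 1L), sample(c("R", "S"), 1L))
  } else {
    aln_all(sample(c("R", "S"), 1L), gen_flat_filler())
  }
}

gen_flat_concept <- function(max_atoms = 3L) {
  aln_and(replicate(sample(seq_len(max_atoms), 1L), gen_flat_atom(),
                    simplify = FALSE))
}

demo_tbox <- local({
  tb <- NULL
  function() {
    if (is.null(tb)) tb <<- build_demo_kg()$tbox
    tb
  }
})

gen_tbox_atom <- function(depth = 2L) {
  names <- c("Eye", "Bone", "CardiovascularSystem", "Kidney", "PDM",
             "Anemia", "NSAID", "BetaBlocker", "Corticosteroid")
  roles <- c("affects", "therapy", "reduces")
  roll <- runif(1)
  if (roll < 0.5 || depth <= 0L) {
    nm <- sample(names, 1L)
    if (runif(1) < 0.3) aln_not(nm) else aln_name(nm)
  } else if (roll < 0.6) {
    aln_min(sample(1:2, 1L), sample(roles, 1L))
  } else if (roll < 0.7) {
    aln_max(sample(0:2, 1L), sample(roles, 1L))
  } else {
    aln_all(sample(roles, 1L), gen_tbox_concept(depth - 1L, max_atoms = 2L))
  }
}

gen_tbox_concept <- function(depth = 2L, max_atoms = 3L) {
  aln_and(replicate(sample(seq_len(max_atoms), 1L), gen_tbox_atom(depth),
                    simplify = FALSE))
}

# a consistent (deep-clash-free) random concept over the demo vocabulary
gen_consistent_concept <- function(tb = demo_tbox(), depth = 2L, max_atoms = 3L) {
  repeat {
    x <- gen_tbox_concept(depth, max_atoms)
    if (!has_deep_clash(x, tb)) return(x)
  }
}
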