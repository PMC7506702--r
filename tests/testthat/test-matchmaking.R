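test_that("penalty follows the declared counting rule", {
  expect_identical(penalty(aln_top()), 0)
  # names and number restrictions count 1; universal restrictions recurse
  expect_equal(penalty(parse_manchester("affects only (CardiovascularSystem and Bone)")), 2)
  expect_equal(penalty(parse_manchester("A and (not B) and (R min 2) and (R max 4)")), 4)
  expect_equal(penalty(parse_manchester("R only (S only (A and B))")), 2)

  # additivity over conjunct-disjoint concepts and monotonicity
  set.seed(606)
  for (i in 1:25) {
    c1 <- gen_flat_concept(); c2 <- gen_flat_concept()
    nf1 <- normalize(c1); nf2 <- normalize(c2); nf12 <- normalize(conjoin(c1, c2))
    if (!nf1$bottom && !nf2$bottom && !nf12$bottom) {
      expect_gte(penalty(conjoin(c1, c2)), penalty(c1))
      disjoint_conjuncts <-
        !length(intersect(c(nf1$pos, nf1$neg), c(nf2$pos, nf2$neg))) &&
        !length(intersect(names(nf1$minc), names(nf2$minc))) &&
        !length(intersect(names(nf1$maxc), names(nf2$maxc))) &&
        !length(intersect(names(nf1$univ), names(nf2$univ)))
      if (disjoint_conjuncts)
        expect_equal(penalty(conjoin(c1, c2)), penalty(c1) + penalty(c2))
    }
  }
})

test_that("contraction reproduces the cortisone give-up/keep split", {
  kg <- build_demo_kg()
  ex <- worked_example("example1", kg)
  ct <- contract(ex$treatment$concept, ex$patient$concept, kg$tbox)
  expect_identical(to_manchester(ct$give_up),
                   "affects only (CardiovascularSystem and Bone)")
  expect_identical(to_manchester(ct$keep),
                   "Corticosteroid and (therapy only Corticosteroid) and (affects only Eye)")
  expect_gt(ct$penalty_cc, 0)
  # G and K recompose the original description
  expect_true(equivalent_concepts(conjoin(ct$give_up, ct$keep),
                                  ex$treatment$concept, kg$tbox))
  # the kept part is compatible with the patient
  expect_false(has_deep_clash(conjoin(ct$keep, ex$patient$concept), kg$tbox))
})

test_that("contraction of a compatible pair is trivial", {
  tb <- demo_tbox()
  d <- parse_manchester("Corticosteroid and (affects only Eye)", tb)
  p <- parse_manchester("PDM and Anemia", tb)
  ct <- contract(d, p, tb)
  expect_identical(ct$give_up$kind, "top")
  expect_identical(ct$penalty_cc, 0)
  expect_true(equivalent_concepts(ct$keep, d, tb))
})

test_that("contraction contracts: G and K recompose D, K compatible with P, G minimal", {
  set.seed(707)
  tb <- demo_tbox()
  for (i in 1:60) {
    d <- gen_consistent_concept(tb)
    p <- gen_consistent_concept(tb)
    ct <- contract(d, p, tb)
    expect_true(equivalent_concepts(conjoin(ct$give_up, ct$keep), d, tb))
    expect_false(has_deep_clash(conjoin(ct$keep, p), tb))
    # minimality: every given-up conjunct individually clashes with P
    for (g in shdss:::concept_conjuncts(ct$give_up))
      expect_true(has_deep_clash(conjoin(unfold(g, tb), conjoin(p, ct$keep)), tb),
                  label = paste("g =", to_manchester(g), "| p =", to_manchester(p)))
  }
})

test_that("abduction returns the structural difference and is minimal", {
  tb <- tbox(roles = "R")
  # full match: nothing to hypothesize
  ab <- abduce(parse_manchester("A and B"), aln_name("A"), tb)
  expect_identical(ab$hypothesis$kind, "top")
  expect_identical(ab$penalty_ca, 0)

  # forced difference
  ab <- abduce(aln_name("A"), parse_manchester("A and B and (R only C)"), tb)
  expect_identical(to_manchester(ab$hypothesis), "B and (R only C)")
  expect_equal(ab$penalty_ca, 2)

  # incompatible inputs demand contraction first
  expect_error(abduce(aln_name("A"), aln_not("A"), tb), "contract")

  set.seed(808)
  tb <- demo_tbox()
  for (i in 1:40) {
    p <- gen_consistent_concept(tb)
    d <- gen_consistent_concept(tb)
    if (has_deep_clash(conjoin(p, d), tb)) next
    ab <- abduce(p, d, tb)
    expect_true(subsumes(d, conjoin(p, ab$hypothesis), tb))
    # minimality: dropping any top-level conjunct of H breaks subsumption
    hs <- shdss:::concept_conjuncts(ab$hypothesis)
    if (length(hs) > 1L)
      for (j in seq_along(hs)) {
        reduced <- aln_and(hs[-j])
        expect_false(subsumes(d, conjoin(p, reduced), tb),
                     label = paste("dropped", to_manchester(hs[[j]])))
      }
  }
})

test_that("match classification is coherent with penalties and compatibility", {
  kg <- build_demo_kg()
  ex <- worked_example("example1", kg)
  m <- match_profiles(ex$treatment$concept, ex$patient$concept, kg$tbox)
  expect_identical(m$type, "partial")
  expect_identical(to_manchester(m$contraction$give_up),
                   "affects only (CardiovascularSystem and Bone)")

  # Thing matches any satisfiable profile fully
  m <- match_profiles(aln_top(), ex$patient$concept, kg$tbox)
  expect_identical(m$type, "full")
  expect_identical(m$contraction$penalty_cc, 0)
  expect_identical(m$abduction$penalty_ca, 0)

  set.seed(909)
  tb <- demo_tbox()
  for (i in 1:40) {
    d <- gen_consistent_concept(tb)
    p <- gen_consistent_concept(tb)
    m <- match_profiles(d, p, tb)
    compatible <- !has_deep_clash(conjoin(d, p), tb)
    expect_identical(m$contraction$penalty_cc == 0, compatible)
    expect_identical(m$type == "partial", !compatible)
    if (m$type == "full") {
      expect_identical(m$abduction$penalty_ca, 0)
      expect_true(subsumes(d, p, tb))
    }
    if (m$type == "potential") expect_gt(m$abduction$penalty_ca, 0)
  }
})
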