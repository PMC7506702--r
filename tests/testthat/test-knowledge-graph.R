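test_that("profile attributes are typed and validated", {
  kg <- build_demo_kg()
  p <- individual_profile("sp", "patient", parse_manchester("PDM and Anemia", kg$tbox),
                          list(age = "54", severity = "2", nickname = "SP"))
  expect_identical(p$attributes$age, 54)        # coerced to numeric
  expect_identical(p$attributes$severity, 2L)   # coerced to integer
  expect_identical(p$attributes$nickname, "SP") # unknown keys preserved

  expect_error(individual_profile("x", "patient", aln_top(), list(severity = 5)),
               "severity.*0 and 4")
  expect_error(individual_profile("x", "patient", aln_top(), list(age = -1)),
               "non-negative")
  expect_error(individual_profile("x", "patient", aln_top(), list(age = "old")),
               "numeric")
})

test_that("annotations round-trip through both syntaxes", {
  kg <- build_demo_kg()
  ex <- worked_example("example1", kg)
  corpus <- c(list(ex$patient, worked_example("example2", kg)$patient,
                   demo_caregiver("rheumatology_nurse", kg)),
              lapply(list_treatments(kg), `[[`, "profile"))
  for (sx in c("manchester", "functional")) {
    for (prof in corpus) {
      doc <- serialize_annotation(prof, sx, kg$kg_iri)
      back <- load_annotation(doc, sx, kg$tbox)
      expect_identical(back$id, prof$id)
      expect_identical(back$category, prof$category)
      expect_true(equivalent_concepts(back$concept, prof$concept, kg$tbox))
      expect_identical(serialize_annotation(back, sx, kg$kg_iri), doc)
    }
  }
})

test_that("annotation loading enforces its contract", {
  kg <- build_demo_kg()
  doc <- serialize_annotation(worked_example("example1", kg)$patient,
                              "manchester", kg$kg_iri)
  # the patient concept survives as parsed structure
  p <- load_annotation(doc, "manchester", kg$tbox)
  expect_identical(to_manchester(p$concept), "PDM and Anemia")

  two <- paste(doc, sub(": sp", ": sp2", doc), sep = "\n")
  expect_error(load_annotation(two, "manchester"), "exactly one individual")
  expect_error(load_annotation("Prefix(:=<x#>)", "functional"), "exactly one ClassAssertion")
  bad <- sub("severity \"2\"", "severity \"5\"", doc)
  expect_error(load_annotation(bad, "manchester"), "severity")
  nocat <- paste(grep("category", strsplit(doc, "\n")[[1]],
                      invert = TRUE, value = TRUE), collapse = "\n")
  expect_error(load_annotation(nocat, "manchester"), "category")
})

test_that("functional serialization is the more compact form on a corpus", {
  kg <- build_demo_kg()
  corpus <- generate_corpus(seed = 11, kg = kg)
  mn <- vapply(corpus, function(p) nchar(serialize_annotation(p, "manchester")), numeric(1))
  fn <- vapply(corpus, function(p) nchar(serialize_annotation(p, "functional")), numeric(1))
  expect_lt(mean(fn), mean(mn))
})

test_that("the cortisone record serializes to its Manchester conjunct set", {
  kg <- build_demo_kg()
  cortisone <- list_treatments(kg)[[1L]]$profile
  doc <- serialize_annotation(cortisone, "manchester", kg$kg_iri)
  expect_match(doc, "Corticosteroid and (therapy only Corticosteroid) and (affects only (Eye and Bone and CardiovascularSystem))",
               fixed = TRUE)
})

test_that("treatment listing is stable and respects exclusions", {
  kg <- build_demo_kg()
  expect_identical(vapply(list_treatments(kg), `[[`, character(1L), "display_name"),
                   c("Cortisone", "Adalimumab", "Ibuprofen"))
  without <- list_treatments(kg, exclude = "cortisone")
  expect_identical(vapply(without, function(tr) tr$profile$id, character(1L)),
                   c("adalimumab", "ibuprofen"))
  expect_identical(list_treatments(kg, exclude = "no-such-id"), list_treatments(kg))
  empty <- smart_health_kg(kg$tbox, list(), kg$kg_iri)
  expect_identical(list_treatments(empty), list())
})

test_that("the KG container validates treatment concepts", {
  kg <- build_demo_kg()
  bad <- treatment_record(
    individual_profile("bad", "treatment",
                       parse_manchester("NSAIDReducedAgent and BetaBlocker", kg$tbox),
                       list(adv_rate = 1)),
    "Clashing")
  expect_error(smart_health_kg(kg$tbox, list(bad)), "unsatisfiable")
})
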