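kg <- build_demo_kg()
ex1 <- worked_example("example1", kg)
ex2 <- worked_example("example2", kg)

test_that("cortisone vs S.P. warns with the printed contraindications", {
  rep <- verify_therapy(ex1$patient, ex1$treatment, kg)
  expect_identical(rep$verdict, "warning")
  expect_setequal(rep$contraindications, c("CardiovascularSystem", "Bone"))
  expect_identical(nrow(rep$interactions), 0L)
  expect_identical(rep$match$type, "partial")
})

test_that("ibuprofen vs C.C. flags the beta-blocker interaction", {
  rep <- verify_therapy(ex2$patient, ex2$treatment, kg)
  expect_identical(rep$verdict, "warning")
  expect_true(any(rep$interactions$role == "reduces" &
                  rep$interactions$class == "BetaBlocker"))
  # and an adverse-indication clash on an affected organ
  expect_true(length(rep$contraindications) >= 1L)
})

test_that("a Thing-described placebo is approved; broken profiles are blocked", {
  placebo <- individual_profile("placebo", "treatment", aln_top(),
                                list(adv_rate = 0))
  rep <- verify_therapy(ex1$patient, placebo, kg)
  expect_identical(rep$verdict, "approved")
  expect_identical(rep$match$contraction$penalty_cc, 0)

  broken <- individual_profile(
    "broken", "patient",
    parse_manchester("NSAIDReducedAgent and BetaBlocker", kg$tbox), list())
  rep <- verify_therapy(broken, placebo, kg)
  expect_identical(rep$verdict, "blocked")
  expect_match(rep$diagnostics, "unsatisfiable")

  expect_error(verify_therapy(ex1$patient, ex1$patient, kg), "treatment profile")
})

test_that("verdict and penalty are coherent over random pairs", {
  set.seed(1010)
  for (i in 1:25) {
    pat <- individual_profile("p", "patient", gen_consistent_concept(kg$tbox),
                              list(age = 40, severity = 2))
    trt <- individual_profile("t", "treatment", gen_consistent_concept(kg$tbox),
                              list(adv_rate = 3))
    rep <- verify_therapy(pat, trt, kg)
    expect_identical(rep$verdict == "approved",
                     rep$match$contraction$penalty_cc == 0)
  }
})

test_that("the utility function evaluates the printed formula", {
  # direct evaluation: ((1+1)/2) * tanh(50/50) * 2 * tanh(10/10)
  m <- structure(list(type = "partial",
                      contraction = list(penalty_cc = 1),
                      abduction = list(penalty_ca = 1)),
                 class = "shdss_match")
  fsc <- compute_fsc(m, list(age = 50, severity = 2), list(adv_rate = 10),
                     max_penalty_ca = 2)
  expect_equal(fsc, 2 * tanh(1)^2, tolerance = 1e-12)
  expect_equal(round(fsc, 5), 1.16005)

  # severity 0 zeroes the score for any treatment
  expect_identical(compute_fsc(m, list(age = 50, severity = 0),
                               list(adv_rate = 10), 2), 0)
  # a zero normalizer zeroes the semantic factor
  expect_identical(compute_fsc(m, list(age = 50, severity = 2),
                               list(adv_rate = 10), 0), 0)

  expect_error(compute_fsc(m, list(severity = 2), list(adv_rate = 1), 2),
               "patient attribute 'age'")
  expect_error(compute_fsc(m, list(age = 50, severity = 2), list(), 2),
               "treatment attribute 'adv_rate'")
})

test_that("fsc is non-negative and monotone in each context factor", {
  m <- structure(list(contraction = list(penalty_cc = 2),
                      abduction = list(penalty_ca = 3)),
                 class = "shdss_match")
  base <- compute_fsc(m, list(age = 50, severity = 2), list(adv_rate = 5), 10)
  expect_gte(base, 0)
  expect_gt(compute_fsc(m, list(age = 80, severity = 2), list(adv_rate = 5), 10), base)
  expect_gt(compute_fsc(m, list(age = 50, severity = 3), list(adv_rate = 5), 10), base)
  expect_gt(compute_fsc(m, list(age = 50, severity = 2), list(adv_rate = 9), 10), base)
  m2 <- structure(list(contraction = list(penalty_cc = 4),
                       abduction = list(penalty_ca = 3)),
                  class = "shdss_match")
  expect_gt(compute_fsc(m2, list(age = 50, severity = 2), list(adv_rate = 5), 10), base)
})

test_that("affinity maps scores onto the descending 0-100% range", {
  expect_identical(affinity_percent(0, c(0, 1)), 100)
  expect_identical(affinity_percent(1, c(0, 1)), 0)
  expect_equal(affinity_percent(0.5, c(0.5, 1.0)), 50)
  expect_identical(affinity_percent(0, c(0, 0)), 100)
  expect_error(affinity_percent(1, numeric()), "non-empty")
})

test_that("suggestions rank adalimumab over cortisone for S.P.", {
  sug <- suggest_alternatives(ex1$patient, kg)
  df <- as.data.frame(sug)
  expect_lt(which(df$treatment == "Adalimumab"), which(df$treatment == "Cortisone"))
  expect_identical(df$affinity_percent, sort(df$affinity_percent, decreasing = TRUE))
  expect_identical(df$fsc, sort(df$fsc))

  # excluded treatment never appears
  sug2 <- suggest_alternatives(ex1$patient, kg, exclude = "cortisone")
  expect_identical(as.data.frame(sug2)$treatment[1L], "Adalimumab")
  expect_false("Cortisone" %in% as.data.frame(sug2)$treatment)

  # single candidate gets affinity 100
  one <- smart_health_kg(kg$tbox, kg$treatments[2L], kg$kg_iri)
  s1 <- suggest_alternatives(ex1$patient, one)
  expect_length(s1, 1L)
  expect_identical(s1[[1L]]$affinity_percent, 100)

  # empty catalogue
  empty <- smart_health_kg(kg$tbox, list(), kg$kg_iri)
  expect_length(suggest_alternatives(ex1$patient, empty), 0L)
})

test_that("ranking is invariant under catalogue permutation", {
  ref <- as.data.frame(suggest_alternatives(ex1$patient, kg))
  set.seed(12)
  for (i in 1:5) {
    perm <- smart_health_kg(kg$tbox, sample(kg$treatments), kg$kg_iri)
    expect_identical(as.data.frame(suggest_alternatives(ex1$patient, perm)), ref)
  }
})

test_that("caregiver authorization follows specialty subsumption and logs denials", {
  nurse <- demo_caregiver("rheumatology_nurse", kg)
  student <- demo_caregiver("medical_student", kg)
  log <- tempfile()
  expect_true(authorize_caregiver(nurse, "Rheumatology", kg, log_path = log))
  expect_false(file.exists(log))
  expect_false(authorize_caregiver(student, "Rheumatology", kg, log_path = log))
  expect_true(file.exists(log))
  expect_match(readLines(log), "event=unauthorized caregiver=medical_student")
  expect_true(authorize_caregiver(student, "Thing", kg))
  expect_error(authorize_caregiver(ex1$patient, "Rheumatology", kg), "caregiver")
})

test_that("reports serialize to the documented JSON shape", {
  rep <- verify_therapy(ex2$patient, ex2$treatment, kg)
  js <- jsonlite::fromJSON(report_to_json(rep))
  expect_identical(js$verdict, "warning")
  expect_identical(js$match$type, "partial")
  expect_true("BetaBlocker" %in% js$interactions$class)
  expect_true(is.numeric(js$match$penalty_cc) && is.numeric(js$match$penalty_ca))
})
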