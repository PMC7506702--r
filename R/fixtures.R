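#' The rheumatology demonstration knowledge graph
#'
#' Builds the bundled mini knowledge graph used throughout the examples
#' and tests: an anatomy taxonomy rooted at `BodyStructure`, connective
#' tissue and blood diseases with vulnerability axioms stating which body
#' systems a disease forbids a therapy from affecting, drug classes with
#' an interaction axiom (NSAIDs reduce the effect of beta blockers,
#' modeled with a disjoint marker class under the `reduces` role),
#' healthcare specialties, and a three-medication catalogue: cortisone
#' (adverse-event rate 6 per 100 patients), adalimumab (1 per 100) and
#' ibuprofen (4 per 100).
#'
#' @param kg_iri IRI for the graph.
#' @return A [smart_health_kg()].
#' @export
build_demo_kg <- function(kg_iri = "http://example.org/sh") {
  tb <- load_ontology(demo_ontology_lines(kg_iri))
  mk <- function(id, name, concept, adv_rate, atc) {
    treatment_record(
      individual_profile(id, "treatment", parse_manchester(concept, tb),
                         list(adv_rate = adv_rate, atc = atc)),
      display_name = name)
  }
  treatments <- list(
    mk("cortisone", "Cortisone",
       "Corticosteroid and (therapy only Corticosteroid) and (affects only (Eye and Bone and CardiovascularSystem))",
       6, "H02AB10"),
    mk("adalimumab", "Adalimumab",
       "AntiTNFalpha and (therapy only AntiTNFalpha) and (affects only (Skin and CardiovascularSystem))",
       1, "L04AB04"),
    mk("ibuprofen", "Ibuprofen",
       "NSAID and (therapy only NSAID) and (affects only (GastrointestinalSystem and Kidney))",
       4, "M01AE01"))
  smart_health_kg(tb, treatments, kg_iri)
}

demo_ontology_lines <- function(kg_iri) {
  anatomy <- c("Eye", "Bone", "CardiovascularSystem", "MusculoskeletalSystem",
               "GastrointestinalSystem", "Kidney", "Skin")
  diseases <- c("Disease", "BloodDisease", "PDM", "Anemia", "MildSLE",
                "MusculoskeletalSystemDisease")
  drugs <- c("Corticosteroid", "AntiTNFalpha", "NSAID", "BetaBlocker",
             "NSAIDReducedAgent")
  people <- c("HealthcareProfessional", "Nurse", "Physician", "Student",
              "MedicalStudent", "MedicalSpecialty", "Rheumatology")
  roles <- c("affects", "therapy", "reduces", "reducedBy", "increases",
             "increaseBy", "seriousEffect")
  c(sprintf("Ontology(<%s>", kg_iri),
    sprintf("Declaration(Class(%s))", c("BodyStructure", anatomy, diseases, drugs, people)),
    sprintf("Declaration(ObjectProperty(%s))", roles),
    sprintf("SubClassOf(%s BodyStructure)", anatomy),
    "SubClassOf(BloodDisease Disease)",
    # disease vulnerability axioms: which body systems a therapy must not touch
    "SubClassOf(PDM ObjectIntersectionOf(Disease ObjectAllValuesFrom(affects ObjectIntersectionOf(ObjectComplementOf(CardiovascularSystem) ObjectComplementOf(Bone)))))",
    "SubClassOf(Anemia ObjectIntersectionOf(BloodDisease ObjectAllValuesFrom(affects ObjectComplementOf(CardiovascularSystem))))",
    "SubClassOf(MildSLE ObjectIntersectionOf(Disease ObjectAllValuesFrom(affects ObjectComplementOf(Kidney))))",
    "SubClassOf(MusculoskeletalSystemDisease ObjectIntersectionOf(Disease ObjectAllValuesFrom(affects ObjectComplementOf(MusculoskeletalSystem))))",
    # drug-class interaction: NSAIDs reduce the effect of beta blockers,
    # expressed through a marker class disjoint with BetaBlocker
    "SubClassOf(NSAID ObjectAllValuesFrom(reduces NSAIDReducedAgent))",
    "DisjointClasses(NSAIDReducedAgent BetaBlocker)",
    # healthcare professionals and specialties
    "SubClassOf(Nurse HealthcareProfessional)",
    "SubClassOf(Physician HealthcareProfessional)",
    "SubClassOf(MedicalStudent Student)",
    "SubClassOf(Rheumatology MedicalSpecialty)",
    ")")
}

#' Demonstration caregiver profiles
#'
#' @param id `"rheumatology_nurse"` (authorized for the rheumatology
#'   ward) or `"medical_student"` (not authorized).
#' @param kg A [smart_health_kg()], used to validate names.
#' @return An [individual_profile()].
#' @export
demo_caregiver <- function(id = c("rheumatology_nurse", "medical_student"),
                           kg = build_demo_kg()) {
  id <- match.arg(id)
  tb <- kg$tbox
  if (id == "rheumatology_nurse")
    individual_profile("rheumatology_nurse", "caregiver",
                       parse_manchester("Nurse and Rheumatology", tb),
                       list(name = "Anna", surname = "Esposito",
                            description = "rheumatology ward nurse"))
  else
    individual_profile("medical_student", "caregiver",
                       parse_manchester("MedicalStudent", tb),
                       list(name = "Luca", surname = "Greco",
                            description = "medical student"))
}

#' The two printed worked examples
#'
#' Example 1: patient S.P. with paraneoplastic dermatomyositis and
#' anemia, proposed therapy cortisone; the contraction must give up
#' `affects only (CardiovascularSystem and Bone)` and keep
#' `Corticosteroid and (therapy only Corticosteroid) and (affects only Eye)`.
#' Example 2: patient C.C. (mild systemic lupus erythematosus, a
#' musculoskeletal disease, and a beta blocker as current medication),
#' proposed therapy ibuprofen; matchmaking must flag the interaction that
#' NSAIDs reduce the effect of beta blockers, plus an adverse-indication
#' clash.
#'
#' @param id `"example1"` or `"example2"`.
#' @param kg A [smart_health_kg()]; defaults to the demo graph.
#' @return A list of class `worked_example` with elements `id`, `patient`,
#'   `treatment`, `expected` (reference report fragments).
#' @export
worked_example <- function(id = c("example1", "example2"), kg = build_demo_kg()) {
  id <- match.arg(id)
  tb <- kg$tbox
  if (id == "example1") {
    patient <- individual_profile("sp", "patient",
                                  parse_manchester("PDM and Anemia", tb),
                                  list(age = 54, severity = 2, gender = "F"))
    treatment <- list_treatments(kg)[[1L]]$profile  # cortisone
    expected <- list(
      give_up = "affects only (CardiovascularSystem and Bone)",
      keep = "Corticosteroid and (therapy only Corticosteroid) and (affects only Eye)",
      contraindications = c("CardiovascularSystem", "Bone"))
  } else {
    cc <- paste("MildSLE and MusculoskeletalSystemDisease",
                "and (seriousEffect only BetaBlocker) and (reduces only BetaBlocker)",
                "and (reducedBy only BetaBlocker) and (increases only BetaBlocker)",
                "and (increaseBy only BetaBlocker)")
    patient <- individual_profile("cc", "patient", parse_manchester(cc, tb),
                                  list(age = 61, severity = 1, gender = "F"))
    treatment <- list_treatments(kg)[[3L]]$profile  # ibuprofen
    expected <- list(interaction_role = "reduces",
                     interaction_class = "BetaBlocker",
                     contraindications = "Kidney")
  }
  structure(list(id = id, patient = patient, treatment = treatment,
                 expected = expected, kg = kg),
            class = "worked_example")
}

#' Deterministic synthetic annotation corpus
#'
#' Generates the pseudo-random corpus used for the compression study:
#' patient, caregiver and treatment profiles drawn from the demo
#' vocabulary, 19 annotations in total by default. Attributes follow the
#' declared realistic ranges — age uniform on 18–90 years, ICF severity
#' uniform on 0–4, adverse-event rate uniform on 0–10 per 100 patients.
#' The corpus is a pure function of its arguments: the same seed yields
#' byte-identical serializations.
#'
#' @param n_patients,n_caregivers,n_treatments Corpus composition
#'   (defaults 8 + 4 + 7 = 19).
#' @param seed Integer seed.
#' @param kg A [smart_health_kg()] providing the vocabulary.
#' @return List of [individual_profile()].
#' @export
generate_corpus <- function(n_patients = 8L, n_caregivers = 4L,
                            n_treatments = 7L, seed = 42L,
                            kg = build_demo_kg()) {
  stopifnot(n_patients + n_caregivers + n_treatments >= 1L)
  tb <- kg$tbox
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  diseases <- c("PDM", "Anemia", "MildSLE", "MusculoskeletalSystemDisease")
  anatomy <- c("Eye", "Bone", "CardiovascularSystem", "MusculoskeletalSystem",
               "GastrointestinalSystem", "Kidney", "Skin")
  drug_classes <- c("Corticosteroid", "AntiTNFalpha", "NSAID", "BetaBlocker")
  first_names <- c("Anna", "Marco", "Giulia", "Paolo", "Sara", "Luca")
  surnames <- c("Rossi", "Bianchi", "Esposito", "Greco", "Conti", "Ricci")
  out <- list()

  for (i in seq_len(n_patients)) {
    dd <- sample(diseases, sample(1:2, 1L))
    parts <- lapply(dd, aln_name)
    if (runif(1) < 0.5)  # current medication, as universal restrictions
      parts <- c(parts, list(aln_all(sample(INTERACTION_ROLES, 1L),
                                     aln_name(sample(drug_classes, 1L)))))
    out <- c(out, list(individual_profile(
      sprintf("patient%02d", i), "patient", aln_and(parts),
      list(age = sample(18:90, 1L), severity = sample(0:4, 1L),
           gender = sample(c("F", "M"), 1L)))))
  }
  for (i in seq_len(n_caregivers)) {
    cpt <- sample(c("Nurse and Rheumatology", "Physician and Rheumatology",
                    "Nurse", "Physician"), 1L)
    out <- c(out, list(individual_profile(
      sprintf("caregiver%02d", i), "caregiver", parse_manchester(cpt, tb),
      list(name = sample(first_names, 1L), surname = sample(surnames, 1L),
           description = sample(c("ward nurse", "attending physician",
                                  "resident"), 1L)))))
  }
  for (i in seq_len(n_treatments)) {
    cls <- sample(setdiff(drug_classes, "BetaBlocker"), 1L)
    aff <- sample(anatomy, sample(1:2, 1L))
    cpt <- aln_and(c(list(aln_name(cls), aln_all("therapy", aln_name(cls))),
                     list(aln_all("affects", aln_and(lapply(aff, aln_name))))))
    out <- c(out, list(individual_profile(
      sprintf("treatment%02d", i), "treatment", cpt,
      list(adv_rate = round(runif(1L, 0, 10), 1L),
           atc = paste0(sample(LETTERS, 1L),
                        sprintf("%02d", sample(0:99, 1L)))))))
  }
  out
}

#' Average compressed annotation sizes over a corpus
#'
#' Serializes every profile in each syntax, compresses with each codec
#' and reports the mean payload size in bytes per (codec, syntax) cell.
#' The `none` row is the mean plain-text size. The report depends only on
#' the corpus contents, not their order.
#'
#' @param corpus List of [individual_profile()] (see [generate_corpus()]).
#' @param syntaxes Subset of `c("functional", "manchester")`.
#' @param codecs Subset of [compress_payload()] codecs.
#' @param kg_iri IRI written into the serializations.
#' @return A data frame: one row per codec, one column per syntax.
#' @export
compression_report <- function(corpus,
                               syntaxes = c("functional", "manchester"),
                               codecs = SUPPORTED_CODECS,
                               kg_iri = "http://example.org/sh") {
  stopifnot(length(corpus) >= 1L)
  syntaxes <- match.arg(syntaxes, c("functional", "manchester"), several.ok = TRUE)
  codecs <- match.arg(codecs, SUPPORTED_CODECS, several.ok = TRUE)
  out <- matrix(NA_real_, nrow = length(codecs), ncol = length(syntaxes),
                dimnames = list(codecs, syntaxes))
  for (sx in syntaxes) {
    docs <- lapply(corpus, serialize_annotation, syntax = sx, kg_iri = kg_iri)
    for (cd in codecs) {
      sizes <- vapply(docs, function(d)
        length(compress_payload(charToRaw(d), cd)), numeric(1L))
      out[cd, sx] <- mean(sizes)
    }
  }
  as.data.frame(out)
}

#' Reference annotation sizes of the original prototype
#'
#' Average serialized annotation sizes in bytes, with and without
#' compression, as reported for the original 19-annotation NFC prototype
#' corpus (which is not published — the synthetic corpus here stands in
#' for it, so only orderings and ratios, not absolute sizes, are
#' comparable). Rows are compression schemes, columns serialization
#' syntaxes; unavailable combinations are `NA`.
#'
#' @return A data frame with a `compression` column and one numeric
#'   column per syntax.
#' @export
reference_annotation_sizes <- function() {
  path <- system.file("extdata", "reference_annotation_sizes.csv",
                      package = "shdss", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Plain-to-compressed ratio from the reference measurements
#'
#' @param syntax Column of [reference_annotation_sizes()].
#' @param codec Compression row to compare against plain text.
#' @return Plain size divided by compressed size.
#' @export
reference_compression_ratio <- function(syntax = "functional", codec = "deflate") {
  tab <- reference_annotation_sizes()
  plain <- tab[tab$compression == "plain", syntax]
  comp <- tab[tab$compression == codec, syntax]
  if (!length(plain) || !length(comp) || is.na(comp))
    stop(sprintf("no reference measurement for %s/%s", syntax, codec), call. = FALSE)
  plain / comp
}
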