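#' Individual profiles
#'
#' An annotation describing one individual — a patient, a caregiver or a
#' treatment — as an ALN concept expression plus extra-logical data
#' attributes. Patient attributes follow the conventions of the workflow:
#' `age` in years (non-negative), `severity` on the WHO ICF impairment
#' scale (integer 0 = none to 4 = complete), optionally `gender` and
#' `weight`. Treatment attributes include `adv_rate`, the incidence of
#' adverse events per 100 patients (non-negative), and the opaque `atc`
#' and `aic` identification codes. Unknown attributes are preserved
#' verbatim: the attribute vocabulary is an open map.
#'
#' @param id Individual IRI or local name (non-empty string).
#' @param category One of `"patient"`, `"caregiver"`, `"treatment"`.
#' @param concept An `aln_concept`.
#' @param attributes Named list of strings or numbers.
#' @return An object of class `individual_profile`.
#' @export
individual_profile <- function(id, category = c("patient", "caregiver", "treatment"),
                               concept, attributes = list()) {
  category <- match.arg(category)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            inherits(concept, "aln_concept"), is.list(attributes))
  if (length(attributes) && is.null(names(attributes)))
    stop("attributes must be a named list", call. = FALSE)
  attributes <- validate_attributes(attributes)
  structure(list(id = id, category = category, concept = concept,
                 attributes = attributes),
            class = "individual_profile")
}

validate_attributes <- function(attrs) {
  num_attr <- function(key, x) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) stop(sprintf("attribute '%s' must be numeric, got '%s'", key, x),
                       call. = FALSE)
    v
  }
  for (key in names(attrs)) {
    val <- attrs[[key]]
    if (key %in% c("age", "adv_rate", "weight", "dosage")) {
      v <- num_attr(key, val)
      if (v < 0) stop(sprintf("attribute '%s' must be non-negative", key), call. = FALSE)
      attrs[[key]] <- v
    } else if (key == "severity") {
      v <- num_attr(key, val)
      if (v != round(v) || v < 0 || v > 4)
        stop("attribute 'severity' must be an integer between 0 and 4 (ICF scale)",
             call. = FALSE)
      attrs[[key]] <- as.integer(v)
    } else {
      attrs[[key]] <- as.character(val)
    }
  }
  attrs
}

#' @export
print.individual_profile <- function(x, ...) {
  cat("<", x$category, "> ", x$id, "\n  ", to_manchester(x$concept), "\n", sep = "")
  if (length(x$attributes)) {
    kv <- vapply(names(x$attributes),
                 function(k) paste0(k, " = ", x$attributes[[k]]), character(1L))
    cat("  ", paste(kv, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

STANDARD_PREFIXES <- c(
  "Prefix: owl: <http://www.w3.org/2002/07/owl#>",
  "Prefix: rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>",
  "Prefix: rdfs: <http://www.w3.org/2000/01/rdf-schema#>",
  "Prefix: xsd: <http://www.w3.org/2001/XMLSchema#>")

#' Serialize an individual annotation
#'
#' Writes a single-individual OWL document in either the Manchester or
#' the functional-style syntax: one class assertion for the profile
#' concept plus one annotation assertion per data attribute (the profile
#' category is carried as the `category` annotation). Output is
#' deterministic — attributes are written in sorted key order — and reads
#' back unchanged through [load_annotation()]. Manchester documents carry
#' the customary standard prefix block, which is why the functional form
#' is the more compact of the two.
#'
#' @param profile An [individual_profile()].
#' @param syntax `"manchester"` or `"functional"`.
#' @param kg_iri IRI of the reference knowledge graph.
#' @return A single string (the document).
#' @export
serialize_annotation <- function(profile, syntax = c("manchester", "functional"),
                                 kg_iri = "http://example.org/sh") {
  syntax <- match.arg(syntax)
  stopifnot(inherits(profile, "individual_profile"))
  attrs <- profile$attributes[order(names(profile$attributes))]
  keys <- names(attrs)
  vals <- vapply(attrs, function(v) format(v, scientific = FALSE, trim = TRUE),
                 character(1L))
  if (syntax == "manchester") {
    lines <- c(
      STANDARD_PREFIXES,
      sprintf("Prefix: : <%s#>", kg_iri),
      sprintf("Ontology: <%s>", kg_iri),
      sprintf("Individual: %s", profile$id),
      sprintf("  Annotations: category \"%s\"", profile$category),
      sprintf("  Annotations: %s \"%s\"", keys, vals),
      sprintf("  Types: %s", to_manchester(profile$concept)))
  } else {
    lines <- c(
      sprintf("Prefix(:=<%s#>)", kg_iri),
      sprintf("Ontology(<%s>", kg_iri),
      sprintf("ClassAssertion(%s %s)", to_functional(profile$concept), profile$id),
      sprintf("AnnotationAssertion(category %s \"%s\")", profile$id, profile$category),
      sprintf("AnnotationAssertion(%s %s \"%s\")", keys, profile$id, vals),
      ")")
  }
  paste(lines, collapse = "\n")
}

#' Load an individual annotation
#'
#' Parses a document produced by [serialize_annotation()] (or equivalent):
#' it must declare exactly one individual with one concept assertion, plus
#' key/value data attributes. Attribute types and ranges are validated
#' (e.g. `severity` outside 0–4 is rejected); unknown attribute keys are
#' kept verbatim.
#'
#' @param payload A single string or character vector of lines.
#' @param syntax `"manchester"` or `"functional"`.
#' @param tbox Optional [tbox()] used to validate concept names.
#' @return An [individual_profile()].
#' @export
load_annotation <- function(payload, syntax = c("manchester", "functional"),
                            tbox = NULL) {
  syntax <- match.arg(syntax)
  lines <- unlist(strsplit(paste(payload, collapse = "\n"), "\n", fixed = TRUE))
  if (syntax == "manchester") parse_annotation_manchester(lines, tbox)
  else parse_annotation_functional(paste(lines, collapse = "\n"), tbox)
}

parse_annotation_manchester <- function(lines, tbox) {
  ind <- grep("^\\s*Individual:", lines)
  if (length(ind) != 1L)
    stop(sprintf("annotation must declare exactly one individual (found %d)",
                 length(ind)), call. = FALSE)
  id <- sub("^:", "", trimws(sub("^\\s*Individual:\\s*", "", lines[ind])))
  typ <- grep("^\\s*Types:", lines)
  if (length(typ) != 1L)
    stop("annotation must carry exactly one Types: assertion", call. = FALSE)
  concept <- parse_manchester(sub("^\\s*Types:\\s*", "", lines[typ]), tbox)
  attrs <- list()
  for (ln in grep("^\\s*Annotations:", lines, value = TRUE)) {
    m <- regmatches(ln, regexec("^\\s*Annotations:\\s*:?([A-Za-z_][A-Za-z0-9_]*)\\s+\"(.*)\"\\s*$", ln))[[1L]]
    if (length(m) != 3L)
      stop(sprintf("malformed annotation line: %s", trimws(ln)), call. = FALSE)
    attrs[[m[2L]]] <- m[3L]
  }
  build_profile_from_attrs(id, concept, attrs)
}

parse_annotation_functional <- function(text, tbox) {
  axioms <- extract_axioms(text)
  heads <- vapply(axioms, `[[`, character(1L), "head")
  ca <- which(heads == "ClassAssertion")
  if (length(ca) != 1L)
    stop(sprintf("annotation must carry exactly one ClassAssertion (found %d)",
                 length(ca)), call. = FALSE)
  sp <- split_functional_args(axioms[[ca]]$body)
  if (length(sp) != 2L)
    stop("ClassAssertion requires a class expression and an individual", call. = FALSE)
  concept <- parse_functional(sp[[1L]], tbox)
  id <- sub("^:", "", trimws(sp[[2L]]))
  attrs <- list()
  for (i in which(heads == "AnnotationAssertion")) {
    m <- regmatches(axioms[[i]]$body,
                    regexec("^\\s*:?([A-Za-z_][A-Za-z0-9_]*)\\s+:?(\\S+)\\s+\"(.*)\"\\s*$",
                            axioms[[i]]$body))[[1L]]
    if (length(m) != 4L)
      stop(sprintf("malformed AnnotationAssertion: %s", axioms[[i]]$body), call. = FALSE)
    if (m[3L] != id)
      stop(sprintf("annotation assertion refers to '%s', expected '%s'", m[3L], id),
           call. = FALSE)
    attrs[[m[2L]]] <- m[4L]
  }
  build_profile_from_attrs(id, concept, attrs)
}

build_profile_from_attrs <- function(id, concept, attrs) {
  category <- attrs[["category"]]
  if (is.null(category))
    stop("annotation is missing the 'category' attribute", call. = FALSE)
  if (!category %in% c("patient", "caregiver", "treatment"))
    stop(sprintf("unknown profile category '%s'", category), call. = FALSE)
  attrs[["category"]] <- NULL
  individual_profile(id, category, concept, attrs)
}

#' Treatment catalogue records
#'
#' @param profile An [individual_profile()] with category `"treatment"`.
#' @param display_name Human-readable medication name.
#' @return An object of class `treatment_record`.
#' @export
treatment_record <- function(profile, display_name) {
  stopifnot(inherits(profile, "individual_profile"),
            is.character(display_name), nzchar(display_name))
  if (profile$category != "treatment")
    stop("treatment records require a profile with category 'treatment'", call. = FALSE)
  structure(list(profile = profile, display_name = display_name),
            class = "treatment_record")
}

#' The Smart-Health knowledge graph container
#'
#' Bundles the terminology, the treatment catalogue and the graph IRI.
#' Every treatment concept must parse against the terminology and be
#' satisfiable with respect to it.
#'
#' @param tbox A [tbox()].
#' @param treatments List of [treatment_record()].
#' @param kg_iri Non-empty IRI string identifying the graph.
#' @return An object of class `smart_health_kg`.
#' @export
smart_health_kg <- function(tbox, treatments = list(),
                            kg_iri = "http://example.org/sh") {
  stopifnot(inherits(tbox, "tbox"), is.list(treatments),
            is.character(kg_iri), nzchar(kg_iri))
  for (tr in treatments) {
    stopifnot(inherits(tr, "treatment_record"))
    if (!is_satisfiable(tr$profile$concept, tbox))
      stop(sprintf("treatment '%s' has an unsatisfiable concept", tr$profile$id),
           call. = FALSE)
  }
  structure(list(tbox = tbox, treatments = treatments, kg_iri = kg_iri),
            class = "smart_health_kg")
}

#' @export
print.smart_health_kg <- function(x, ...) {
  cat("<smart_health_kg> ", x$kg_iri, "\n", sep = "")
  print(x$tbox)
  cat("  treatments:  ",
      paste(vapply(x$treatments, `[[`, character(1L), "display_name"), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' List catalogue treatments
#'
#' Returns the treatment catalogue in its stable stored order, optionally
#' excluding one treatment by profile id (the medication under scrutiny
#' is excluded when searching for substitutes). An exclusion id that does
#' not occur leaves the list unchanged.
#'
#' @param kg A [smart_health_kg()].
#' @param exclude Optional treatment profile id to drop.
#' @return List of [treatment_record()].
#' @export
list_treatments <- function(kg, exclude = NULL) {
  stopifnot(inherits(kg, "smart_health_kg"))
  out <- kg$treatments
  if (!is.null(exclude))
    out <- Filter(function(tr) tr$profile$id != exclude, out)
  out
}
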