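#' Interaction roles recognized by the workflow
#'
#' Contraindications are derived only from the `affects` role; therapy
#' interactions only from the roles listed here.
#'
#' @export
INTERACTION_ROLES <- c("reduces", "reducedBy", "increases", "increaseBy",
                       "seriousEffect")

#' Utility-function parameters
#'
#' Tunable damping weights of the ranking utility: `alpha` (years)
#' controls how quickly patient age saturates its `tanh` factor, `beta`
#' (adverse events per 100 patients) does the same for the adverse-event
#' rate. The defaults, 50 and 10, are the empirically suggested values.
#'
#' @param alpha Positive number, default 50.
#' @param beta Positive number, default 10.
#' @return A list of class `score_params`.
#' @export
score_params <- function(alpha = 50, beta = 10) {
  stopifnot(is.numeric(alpha), alpha > 0, is.numeric(beta), beta > 0)
  structure(list(alpha = alpha, beta = beta), class = "score_params")
}

#' Verify a proposed therapy against a patient profile
#'
#' Runs the matchmaking classification of the treatment description
#' against the patient profile, then translates the conflicting part into
#' a practitioner-facing explanation: clashes under `affects` become
#' contraindications (the anatomical structures actually at risk), and
#' clashes under an interaction role become therapy interactions with the
#' medication class the patient is already taking. The verdict is
#' `"approved"` exactly when nothing clashes (penaltyCC = 0),
#' `"warning"` otherwise, and `"blocked"` when the patient profile is
#' itself inconsistent.
#'
#' @param patient [individual_profile()] with category `"patient"`.
#' @param treatment [individual_profile()] with category `"treatment"`.
#' @param kg A [smart_health_kg()].
#' @param log_path Optional audit-log file; warning/blocked events are
#'   appended as single-line records.
#' @return A list of class `verification_report` with elements `verdict`,
#'   `contraindications` (character), `interactions` (data frame with
#'   columns `role`, `class`), `match` and `diagnostics`.
#' @export
verify_therapy <- function(patient, treatment, kg, log_path = NULL) {
  stopifnot(inherits(patient, "individual_profile"),
            inherits(treatment, "individual_profile"),
            inherits(kg, "smart_health_kg"))
  if (patient$category != "patient" || treatment$category != "treatment")
    stop("verify_therapy() requires a patient profile and a treatment profile",
         call. = FALSE)
  tb <- kg$tbox
  if (has_deep_clash(patient$concept, tb)) {
    rep <- structure(list(verdict = "blocked", contraindications = character(),
                          interactions = empty_interactions(), match = NULL,
                          diagnostics = "patient profile is unsatisfiable with respect to the terminology"),
                     class = "verification_report")
    audit_log(log_path, event = "blocked", caregiver = NA, patient = patient$id,
              treatment = treatment$id, verdict = "blocked")
    return(rep)
  }
  match <- match_profiles(treatment$concept, patient$concept, tb)
  expl <- explain_conflicts(match$contraction$give_up, patient, tb)
  verdict <- if (match$contraction$penalty_cc == 0) "approved" else "warning"
  if (verdict != "approved")
    audit_log(log_path, event = "warning", caregiver = NA, patient = patient$id,
              treatment = treatment$id, verdict = verdict)
  structure(list(verdict = verdict,
                 contraindications = expl$contraindications,
                 interactions = expl$interactions,
                 match = match, diagnostics = NULL),
            class = "verification_report")
}

empty_interactions <- function() {
  data.frame(role = character(), class = character(), stringsAsFactors = FALSE)
}

# map give-up conjuncts to contraindication / interaction entries
explain_conflicts <- function(give_up, patient, tb) {
  contra <- character()
  inter <- empty_interactions()
  psurf <- normalize(patient$concept)
  punf <- normalize(unfold(patient$concept, tb))
  patient_classes <- function(role) {
    f <- psurf$univ[[role]]
    if (!is.null(f) && length(f$pos)) return(f$pos)
    f <- punf$univ[[role]]
    if (!is.null(f)) f$pos else character()
  }
  for (g in concept_conjuncts(give_up)) {
    if (g$kind == "all" && g$role == "affects") {
      contra <- union(contra, normalize(g$filler)$pos)
      next
    }
    if (g$kind == "all" && g$role %in% INTERACTION_ROLES) {
      inter <- rbind(inter, data.frame(role = g$role,
                                       class = patient_classes(g$role),
                                       stringsAsFactors = FALSE))
      next
    }
    # clash introduced through the axioms of a named class (e.g. a drug
    # class whose interaction axiom lives in the terminology)
    gu <- normalize(unfold(g, tb))
    for (r in names(gu$univ)) {
      pf <- punf$univ[[r]]
      if (is.null(pf)) next
      comb <- normalize(conjoin(nf_to_concept(gu$univ[[r]]), nf_to_concept(pf)))
      if (!deep_clash_nf(comb)) next
      if (r == "affects") {
        contra <- union(contra, intersect(gu$univ[[r]]$pos, pf$neg))
      } else if (r %in% INTERACTION_ROLES) {
        inter <- rbind(inter, data.frame(role = r, class = patient_classes(r),
                                         stringsAsFactors = FALSE))
      }
    }
  }
  inter <- unique(inter)
  rownames(inter) <- NULL
  list(contraindications = contra, interactions = inter)
}

#' @export
print.verification_report <- function(x, ...) {
  cat("<therapy verification> verdict: ", x$verdict, "\n", sep = "")
  if (length(x$contraindications))
    cat("  contraindications (affects): ",
        paste(x$contraindications, collapse = ", "), "\n", sep = "")
  if (nrow(x$interactions))
    cat("  interactions: ",
        paste(sprintf("%s -> %s", x$interactions$role, x$interactions$class),
              collapse = "; "), "\n", sep = "")
  if (!is.null(x$diagnostics)) cat("  ", x$diagnostics, "\n", sep = "")
  if (!is.null(x$match)) print(x$match)
  invisible(x)
}

#' Context-aware utility score
#'
#' Combines the semantic penalties with the contextual attributes:
#' \deqn{fsc = \frac{penaltyCC + penaltyCA}{maxpenaltyCA}
#'   \cdot \tanh(age/\alpha) \cdot severity \cdot \tanh(adv\_rate/\beta)}
#' Lower values indicate better matches. `max_penalty_ca` is the highest
#' abduction penalty among the candidate medications; when it is zero the
#' first factor is zero. Missing required attributes raise an error that
#' names the attribute.
#'
#' @param match A [match_profiles()] result.
#' @param patient_attrs Named list with `age` (years) and `severity`
#'   (ICF 0–4).
#' @param treatment_attrs Named list with `adv_rate` (per 100 patients).
#' @param max_penalty_ca Non-negative number.
#' @param params A [score_params()].
#' @return A single non-negative number.
#' @export
compute_fsc <- function(match, patient_attrs, treatment_attrs,
                        max_penalty_ca, params = score_params()) {
  stopifnot(inherits(match, "shdss_match"), inherits(params, "score_params"),
            is.numeric(max_penalty_ca), max_penalty_ca >= 0)
  need <- function(attrs, key, who) {
    v <- attrs[[key]]
    if (is.null(v)) stop(sprintf("missing required %s attribute '%s'", who, key),
                         call. = FALSE)
    as.numeric(v)
  }
  age <- need(patient_attrs, "age", "patient")
  severity <- need(patient_attrs, "severity", "patient")
  adv_rate <- need(treatment_attrs, "adv_rate", "treatment")
  stopifnot(age >= 0, severity %in% 0:4, adv_rate >= 0)
  pen <- match$contraction$penalty_cc + match$abduction$penalty_ca
  f1 <- if (max_penalty_ca == 0) 0 else pen / max_penalty_ca
  f1 * tanh(age / params$alpha) * severity * tanh(adv_rate / params$beta)
}

#' Affinity percentage
#'
#' Converts a utility score into the ascending 0–100% affinity shown to
#' practitioners: `100 * (1 - fsc / max(fsc_values))`, with 100 when all
#' scores in the query are zero.
#'
#' @param fsc A score from the current query.
#' @param fsc_values All scores of the current query (must contain `fsc`).
#' @return A number in \[0, 100\].
#' @export
affinity_percent <- function(fsc, fsc_values) {
  if (!length(fsc_values)) stop("fsc_values must be non-empty", call. = FALSE)
  m <- max(fsc_values)
  if (m == 0) return(100)
  100 * (1 - fsc / m)
}

#' Ranked substitute-therapy suggestions
#'
#' Matches every catalogue treatment (minus an optional exclusion)
#' against the patient, scores each with [compute_fsc()] — normalizing by
#' the highest abduction penalty over the candidate set — and returns the
#' candidates sorted ascending by score (best first). Ties are broken
#' deterministically by raw semantic penalty, then adverse-event rate,
#' then display name, so the ranking is invariant under catalogue
#' permutation.
#'
#' @param patient [individual_profile()] with category `"patient"`.
#' @param kg A [smart_health_kg()].
#' @param exclude Optional treatment id to leave out (e.g. the medication
#'   just flagged).
#' @param params A [score_params()].
#' @param log_path Optional audit-log file passed to [verify_therapy()].
#' @return A list of class `ranked_suggestions`; each element has
#'   `treatment`, `fsc`, `affinity_percent`, `adv_rate` and `explanation`
#'   (a `verification_report`).
#' @export
suggest_alternatives <- function(patient, kg, exclude = NULL,
                                 params = score_params(), log_path = NULL) {
  stopifnot(inherits(patient, "individual_profile"), inherits(kg, "smart_health_kg"))
  cands <- list_treatments(kg, exclude)
  if (!length(cands)) return(structure(list(), class = "ranked_suggestions"))
  reports <- lapply(cands, function(tr)
    verify_therapy(patient, tr$profile, kg, log_path = log_path))
  pca <- vapply(reports, function(r) r$match$abduction$penalty_ca, numeric(1L))
  max_pca <- max(pca)
  fsc <- vapply(seq_along(cands), function(i)
    compute_fsc(reports[[i]]$match, patient$attributes,
                cands[[i]]$profile$attributes, max_pca, params), numeric(1L))
  adv <- vapply(cands, function(tr) as.numeric(tr$profile$attributes$adv_rate),
                numeric(1L))
  pen <- vapply(reports, function(r)
    r$match$contraction$penalty_cc + r$match$abduction$penalty_ca, numeric(1L))
  nm <- vapply(cands, `[[`, character(1L), "display_name")
  ord <- order(fsc, pen, adv, nm)
  out <- lapply(ord, function(i) {
    # a sole option has nothing to be ranked against: full affinity
    aff <- if (length(cands) == 1L) 100 else affinity_percent(fsc[i], fsc)
    list(treatment = cands[[i]], fsc = fsc[i],
         affinity_percent = aff,
         adv_rate = adv[i], explanation = reports[[i]])
  })
  structure(out, class = "ranked_suggestions")
}

#' @export
print.ranked_suggestions <- function(x, ...) {
  if (!length(x)) { cat("<suggestions> (empty)\n"); return(invisible(x)) }
  df <- as.data.frame(x)
  cat("<suggestions> best first\n")
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.ranked_suggestions <- function(x, ...) {
  data.frame(
    treatment = vapply(x, function(s) s$treatment$display_name, character(1L)),
    fsc = vapply(x, `[[`, numeric(1L), "fsc"),
    affinity_percent = vapply(x, `[[`, numeric(1L), "affinity_percent"),
    adv_rate = vapply(x, `[[`, numeric(1L), "adv_rate"),
    verdict = vapply(x, function(s) s$explanation$verdict, character(1L)),
    stringsAsFactors = FALSE)
}

#' Caregiver authorization
#'
#' A caregiver may operate the system when their profile concept is
#' subsumed by the required specialty class; a denial is appended to the
#' audit log.
#'
#' @param caregiver [individual_profile()] with category `"caregiver"`.
#' @param required_specialty A concept name (string) or `aln_concept`;
#'   `"Thing"` authorizes everyone.
#' @param kg A [smart_health_kg()].
#' @param log_path Optional audit-log file.
#' @return Logical.
#' @export
authorize_caregiver <- function(caregiver, required_specialty, kg,
                                log_path = NULL) {
  stopifnot(inherits(caregiver, "individual_profile"), inherits(kg, "smart_health_kg"))
  if (caregiver$category != "caregiver")
    stop("authorize_caregiver() requires a caregiver profile", call. = FALSE)
  req <- if (inherits(required_specialty, "aln_concept")) required_specialty
         else if (identical(required_specialty, "Thing")) aln_top()
         else aln_name(required_specialty)
  ok <- subsumes(req, caregiver$concept, kg$tbox)
  if (!ok)
    audit_log(log_path, event = "unauthorized", caregiver = caregiver$id,
              patient = NA, treatment = NA, verdict = "blocked")
  ok
}

# single-line structured audit records; no-op when path is NULL
audit_log <- function(path, event, caregiver = NA, patient = NA,
                      treatment = NA, verdict = NA) {
  if (is.null(path)) return(invisible(NULL))
  line <- sprintf("ts=%s event=%s caregiver=%s patient=%s treatment=%s verdict=%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), event,
                  caregiver, patient, treatment, verdict)
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(line)
}

#' JSON form of a verification report
#'
#' The documented machine-readable shape emitted by the command-line
#' tools: verdict, contraindications, interactions, match type, both
#' penalties and the Give-up/Keep/Hypothesis strings in Manchester
#' syntax.
#'
#' @param report A `verification_report`.
#' @return A JSON string.
#' @export
report_to_json <- function(report) {
  stopifnot(inherits(report, "verification_report"))
  x <- list(verdict = report$verdict,
            contraindications = report$contraindications,
            interactions = report$interactions,
            diagnostics = report$diagnostics)
  if (!is.null(report$match)) {
    x$match <- list(
      type = report$match$type,
      penalty_cc = report$match$contraction$penalty_cc,
      penalty_ca = report$match$abduction$penalty_ca,
      give_up = to_manchester(report$match$contraction$give_up),
      keep = to_manchester(report$match$contraction$keep),
      hypothesis = to_manchester(report$match$abduction$hypothesis))
  }
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"))
}
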