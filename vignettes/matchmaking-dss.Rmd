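---
title: "Description-logic matchmaking for therapy verification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Description-logic matchmaking for therapy verification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shdss)
```

## The problem

At the point of care, a practitioner about to administer a medication
needs two checks done instantly and without a network round-trip: does
this drug clash with the patient's conditions (contraindications), and
does it interfere with what the patient already takes (interactions)?
`shdss` implements a knowledge-based answer. Patient records, caregiver
badges and medication packagings are modeled as OWL annotations carried
on NFC tags (here, byte buffers on disk); a small embedded reasoner
classifies the match between a medication description $D$ and a patient
profile $P$ and, when the proposed therapy is problematic, ranks
substitutes.

## The logic and its normal form

Annotations live in the ALN description logic: concept names, atomic
negation, conjunction, universal role restrictions ($\forall R.C$) and
unqualified number restrictions ($\geq n\,R$, $\leq n\,R$). This
fragment is deliberately small — subsumption is decidable by structural
comparison, cheap enough for embedded use — and is enforced at the
parser boundary: `or`, `some`, qualified cardinality or nominals are
hard syntax errors.

Reasoning works on a conjunctive normal form (`normalize()`): flattened
conjunctions, merged universal fillers per role
($\forall R.C_1 \sqcap \forall R.C_2 \to \forall R.(C_1 \sqcap C_2)$),
tightest cardinality bounds, and three clash rules — $\{A, \neg A\}$ at
one level, $\min > \max$ on a role, and a minimum cardinality $\geq 1$
on a role whose filler is unsatisfiable. Terminologies are acyclic;
`unfold()` eliminates defined names before normalization. Two design
choices here deserve justification:

* **Disjointness as atomic negation.** ALN has no general negation, so
  `DisjointClasses(A, B)` is compiled at unfolding time: every
  occurrence of `A` gains `not B` and vice versa. This reproduces the
  clash behaviour of disjoint classes entirely inside the fragment, and
  it is the mechanism behind both contraindication and interaction
  detection.
* **Inclusion markers.** A primitive inclusion `A ⊑ C` unfolds to
  `A ⊓ C`, retaining `A` itself. The marker keeps explanations
  human-readable: a contraction can report the *named* class a conflict
  came from instead of its anonymous expansion.

A third choice concerns $\forall R.\bot$. Semantically, a concept whose
filler for `R` is unsatisfiable is still satisfiable — it simply has no
`R` successors — and `is_satisfiable()` follows that semantics (it
agrees with a brute-force model-enumeration oracle in the tests). The
matchmaking layer, however, uses a stricter compatibility test,
`has_deep_clash()`, that flags a clash at *any* filler depth. The reason
is clinical, not logical: an interaction between a proposed NSAID and a
patient's beta blocker lives entirely inside the `reduces` filler. No
cardinality forces that role to be populated, so the conjunction
$D \sqcap P$ stays globally satisfiable — yet the clash is exactly the
signal the system exists to raise. Treating "no clash at any depth" as
the compatibility criterion makes the worked examples come out as a
practitioner would expect.

## Contraction, abduction, penalties

When $D$ and $P$ are incompatible, **Concept Contraction** splits $D$
into $\langle G, K \rangle$: `G` (give up) collects the conjuncts that
clash with $P$, `K` (keep) the rest, recursing into universal fillers
shared by both sides. The algorithm gives up as little as possible —
every conjunct moved to `G` individually clashes with $P$ — and
`G ⊓ K ≡ D` holds by construction. When the (possibly contracted)
description is compatible, **Concept Abduction** computes the
hypothesis `H`: the structural difference between the description and
the profile, minimal in the sense that dropping any conjunct of `H`
breaks `subsumes(D, P ⊓ H)`.

Two presentation choices:

* **Surface reporting.** `G`, `K` and `H` are expressed over the
  *surface* conjuncts of the description (what the annotation actually
  says), while clash and entailment tests run on unfolded forms.
  Unfolding injects taxonomy markers — every anatomical name carries its
  `BodyStructure` superclass — which belong in the reasoning but not in
  an explanation shown to a nurse.
* **Ordering.** Give-up conjuncts are ordered by the position of the
  conflicting constraint in the patient profile; keep conjuncts retain
  description order. This makes reports deterministic and matches how a
  reader scans a conflict list: by what in the *patient* caused it.

Penalties measure semantic distance: each (negated) concept name and
each number restriction counts one; a universal restriction contributes
the penalty of its filler; `Thing` scores zero. Penalties are computed
on unfolded normal forms, so a clash against a deeply modeled class
weighs more than one against a bare name. The rule is additive over
disjoint conjunctions, order-independent and zero exactly on full
matches — all the downstream utility function needs. Richer weightings
(e.g. depth-discounted) would slot into `penalty()` without touching
the rest.

## The verification workflow and the utility function

`verify_therapy()` classifies the match and translates `G` into the
practitioner-facing report: positive names in the `affects` filler of
`G` become contraindications; clashes under the interaction roles
(`reduces`, `reducedBy`, `increases`, `increaseBy`, `seriousEffect`)
become interactions, labelled with the medication class found in the
patient's corresponding filler. The verdict is `approved` exactly when
`penaltyCC = 0`, `warning` otherwise, `blocked` for an inconsistent
patient profile (and for an unauthorized caregiver at the CLI level,
where denials are also written to the audit log).

Ranking combines the penalties with context through

$$
fsc \;=\; \frac{penaltyCC + penaltyCA}{maxpenaltyCA}
\cdot \tanh\!\left(\frac{age}{\alpha}\right) \cdot severity
\cdot \tanh\!\left(\frac{adv\_rate}{\beta}\right),
$$

lower being better. The factor-by-factor reading (severity multiplies
*outside* the hyperbolic tangents) follows the prose description of the
score's components; the damping parameters default to $\alpha = 50$
years and $\beta = 10$ adverse events per 100 patients, the empirically
suggested values, and saturate the age and adverse-rate contributions
smoothly instead of letting outliers dominate. `maxpenaltyCA` is the
largest abduction penalty over the candidate set of the *current* query
(the catalogue minus exclusions) — per-query normalization keeps scores
comparable within the list actually shown.

Degenerate cases are kept explicit rather than patched over:

* `severity = 0` zeroes every score; the ranking then falls back on the
  deterministic tie-break (raw semantic penalty, then adverse-event
  rate, then name).
* A query with a single candidate reports 100% affinity: with nothing
  to rank against, the `100·(1 − fsc/\max fsc)` mapping would call the
  only option 0% — misleading for a sole viable therapy.
* `maxpenaltyCA = 0` (every candidate fully matches) zeroes the
  semantic factor.

## The NDEF layer

Tags carry one MIME-typed NDEF record (TNF = 2). The Type field holds
the OWL MIME type of the serialization (`text/owl-manchester`,
`text/owl-functional`, …) plus a `;codec=` parameter naming the
compression — the wire format nowhere else says how the payload was
compressed, and a MIME parameter keeps the record self-describing and
standards-legal. The record ID is `"<kg-iri>#<task>"`, so a reader can
filter tags by task (patients, caregivers, treatments) without
decompressing anything. Records of other TNFs pass through the decoder
untouched, preserving legacy NFC content; chunked records are decoded
but never produced, since a single annotation always fits one record.

Three codecs are supported besides identity: *deflate* (the zlib
framing, 6 bytes of overhead), *gzip* (the same stream in gzip framing,
18 bytes — the constant 12-byte difference is why deflate wins on every
corpus), and *lzma* (xz container, which only pays off on much larger
documents). All three are produced through R's built-in zlib/liblzma
bindings; the gzip member is framed with a real CRC32 so external tools
accept it.

## Synthetic data: what it emulates and what it does not

`build_demo_kg()` encodes the rheumatology vocabulary of the worked
examples: disease vulnerability axioms are universal restrictions over
`affects` with negated anatomy (paraneoplastic dermatomyositis forbids
touching the cardiovascular system and bone; anemia the cardiovascular
system; mild lupus the kidney), and the NSAID/beta-blocker interaction
is a marker class under `reduces` declared disjoint with `BetaBlocker`.
These are the minimal encodings that yield the documented conflict
sets; any encoding producing the same clashes would do.

`generate_corpus()` produces the 19-annotation corpus (8 patients, 4
caregivers, 7 treatments) used in the compression study, with age
uniform on 18–90 years, ICF severity uniform on 0–4 and adverse-event
rates uniform on 0–10 per 100 patients — a scientist's defaults for a
plausible ward population, fixed once. The corpus is a pure function of
its seed.

What the synthetic corpus does *not* emulate: the original prototype's
19 annotations are unpublished, and real annotations import large
vocabularies (SNOMED-CT, UBERON, ChEBI) whose IRIs and boilerplate
dominate byte counts. Absolute sizes here are therefore not comparable
to the bundled reference measurements
(`reference_annotation_sizes()`); only *orderings and ratios* are —
deflate below gzip below lzma for text this size, functional as the
most compact plain syntax, and the 2.79 plain-to-deflate ratio on the
functional syntax, which is computed from the reference table itself.
Passing tests consequently show the algorithms' contracts and the
format orderings, not byte-level agreement with any external corpus.

## Numerical and testing choices

* The model-enumeration oracle used to validate satisfiability and
  subsumption enumerates every interpretation over a concept's own
  signature for domain sizes 1–2. The concept families compared against
  it are restricted (number bounds ≤ 1–2 at top level, flat universal
  fillers, pairwise conjunctions) so that a satisfying or counter model,
  when one exists, fits in two elements — making the small-domain oracle
  complete for exactly the fragment it is asked about.
* Property suites run 1000 random contraction/abduction pairs and a
  systematic atom-pair family (3 names, 2 roles, depth ≤ 2); both
  complete in well under a minute on one CPU. Problem sizes were chosen
  so the whole suite stays interactive.
* All randomness is seeded; rankings, serializations and tag encodings
  are deterministic given their inputs, and the corpus generator
  restores the caller's RNG state.

## Known limitations

* No general OWL 2 reasoning: no disjunction, existentials, qualified
  cardinality, nominals or role hierarchies, and no ABox consistency
  checking beyond profile-versus-concept matching.
* The terminology must be acyclic; cycles are rejected at load time.
* The penalty rule is a declared convention, not fitted to data.
* The utility model is explicitly not applicable to pediatric patients
  (the age factor only dampens *upwards* from zero).
* Negation of *defined* names is outside the fragment; negated names
  are treated as primitive.
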