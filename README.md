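# shdss — knowledge-based therapy verification over semantic NFC tags

`shdss` is a clinical decision support toolkit for the bedside question
*"can I give this patient this drug?"*. Patient records, caregiver
badges and medication packagings are modeled as OWL annotations in the
ALN description logic and carried on NFC tags (emulated here as byte
buffers) as compressed NDEF payloads. A structural reasoner detects
contraindications and drug interactions, explains them, and ranks
substitute therapies — all without a back-end server.

## The method

A medication description *D* and a patient profile *P* are compared by
two non-standard inferences:

* **Concept Contraction** — when *D* and *P* clash, split *D* into
  ⟨*G*, *K*⟩: *G* ("give up") is the conflicting part, *K* ("keep") the
  largest remainder compatible with *P*.
* **Concept Abduction** — when compatible, compute the hypothesis *H*
  that *P* would need for a full match with *D* (or with *K* after a
  contraction).

Penalty scores on *G* and *H* (`penaltyCC`, `penaltyCA`) measure
semantic distance. Candidates are ranked by the context-aware utility

```
fsc = (penaltyCC + penaltyCA) / maxpenaltyCA
      · tanh(age/α) · severity · tanh(adv_rate/β)
```

with α = 50 years, β = 10 adverse events per 100 patients, `severity`
the WHO ICF impairment level (0–4) and `adv_rate` the medication's
adverse-event incidence per 100 patients. Lower is better; scores are
shown as an ascending 0–100 % affinity.

Conflicts are found through terminology design: diseases carry
universal restrictions over `affects` with *negated* anatomy (what a
therapy must not touch), and drug-class interactions use disjoint
marker classes under roles such as `reduces` — so a clash inside a role
filler is exactly a contraindication or interaction, and the
contraction names it.

## A worked example

A patient with paraneoplastic dermatomyositis (PDM) and anemia;
the proposed therapy is cortisone, whose annotation warns about eyes,
bone and the cardiovascular system:

```r
library(shdss)
kg <- build_demo_kg()
ex <- worked_example("example1", kg)   # patient "PDM and Anemia", cortisone
verify_therapy(ex$patient, ex$treatment, kg)
#> <therapy verification> verdict: warning
#>   contraindications (affects): CardiovascularSystem, Bone
#> <match> type = partial, penaltyCC = 3, penaltyCA = 4
#>   Give up: affects only (CardiovascularSystem and Bone)
#>   Keep:    Corticosteroid and (therapy only Corticosteroid) and (affects only Eye)
#>   Hypothesis: Corticosteroid and (therapy only Corticosteroid) and (affects only Eye)
```

PDM forbids affecting the cardiovascular and skeletal systems and the
blood disease forbids the cardiovascular system, so the reasoner
retracts exactly the `affects only (CardiovascularSystem and Bone)`
part of the cortisone description and keeps the rest. Asking for
alternatives ranks the catalogue by `fsc`:

```r
as.data.frame(suggest_alternatives(ex$patient, kg))
#>    treatment       fsc affinity_percent adv_rate  verdict
#> 1 Adalimumab 0.1054088        84.092770        1  warning
#> 2  Ibuprofen 0.6027503         9.038972        4 approved
#> 3  Cortisone 0.6626468         0.000000        6  warning
```

Adalimumab also carries a (smaller) cardiovascular risk, but its
adverse-event rate of 1 in 100 versus cortisone's 6 in 100 puts it
first. A second bundled example (`worked_example("example2")`) shows
interaction detection: ibuprofen proposed for a patient on a beta
blocker is flagged with `(reduces, BetaBlocker)`.

The same workflow runs from a shell on tag files:

```sh
inst/cli/shdss demo --dir demo
inst/cli/shdss verify --patient demo/patient_sp.ndef \
    --treatment demo/treatment_cortisone.ndef \
    --caregiver demo/caregiver_nurse.ndef      # exit 1 = warning
inst/cli/shdss suggest --patient demo/patient_sp.ndef --exclude cortisone
```

Exit codes: 0 approved, 1 warning, 2 blocked/unauthorized, 3 usage or
decode errors.

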