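---
title: "The microbiology data model: design, terminology and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The microbiology data model: design, terminology and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microfhir)
```

## The model

Microbiology laboratory results fall into three main diagnostic blocks —
culture (detection, colony count, antimicrobial susceptibility, microscopy),
molecular diagnostics, and serology/immunology — plus a further-properties
group characterizing a detected organism: MDRO typing, MRGN classification,
resistance mechanisms and virulence factors. `observation_kinds()` is the
registry of the ten observation kinds over these four blocks; each kind maps
to one FHIR R4 Observation profile, and a DiagnosticReport collects results
per study type.

Two result styles recur and are deliberately kept distinct: detection-style
kinds (culture, microscopy, virulence factor) use the three-valued
detected / not detected / inconclusive set, while positivity-style kinds
(molecular, serology, resistance mechanism) use the four-valued positive /
weakly positive / negative / inconclusive set. Mixing them is one of the
commonest real-world data errors, so the split is both a constructor
invariant and a validator rule (`result-vs-mismatch`).

Patient, encounter and specimen are cross-module concerns and are carried as
opaque reference strings, never modelled. Identifiers are caller-supplied;
the library invents none outside the seeded synthetic module.

## Terminology engine

Snapshots are flat TSV files: hierarchical (code, display, pipe-separated
parents; the is-a graph must be acyclic) or tabular (code, display, and the
Property / Method / Class / Component part axes). The format is hand-editable
and diff-friendly on purpose. Value sets are either extensional
(enumerated) or intensional (rule-defined); the rule language is exactly as
large as the model needs:

* hierarchical rules support `<` (strict descendants), `<<`
  (descendant-or-self) and subtree exclusion — no further expression
  constraint grammar;
* exclusions are descendant-or-self and dominate inclusions: an excluded
  sub-group is removed root and all;
* tabular rules are conjunctions of `equals` / `not-equals` / `in`
  constraints on part values, matched case-insensitively (part values appear
  in mixed case in the wild, e.g. "susc" vs "Susc").

`valueset_contains()` answers membership without materializing the
expansion (upward ancestor walk, single parts-row check); an
expand/contains agreement property is tested exhaustively over the shipped
catalog and fixture snapshot. Unknown codes *raise* rather than return
`FALSE`, so a snapshot/catalog mismatch surfaces at the first query instead
of silently passing validation.

The organism value set is the organism hierarchy minus exactly five excluded
sub-groups (Domain Archaea, Kingdom Animalia, Kingdom Plantae, Kingdom
Viridiplantae, Slime mold); no depth constraint is applied. The
susceptibility-test rule applies exactly two constraints (Property equals
"Susc", Method not-equals "Genotyping") and nothing more. Both choices keep
the rules minimal rather than speculative.

## Terminology bindings worth explaining

* **Susceptibility interpretation.** Two category systems coexist: the
  three-valued EUCAST set (S, I, R — with I meaning "intermediate /
  susceptible - increased exposure" in recent versions) and the five-valued
  CLSI-style set (S, SDD, I, R, NS). Because the category definitions have
  changed over the years, the standard's version is mandatory whenever an
  interpretation is recorded; it travels in `coding.version`. EUCAST
  publishes no code system, so a small self-defined draft CodeSystem is
  shipped as a fixture (`inst/extdata/eucast_codesystem.json`); CLSI-style
  values use the HL7 v3 ObservationInterpretation system. The validator
  detects the scheme from `coding.system` and treats an unrecognized system
  as an error, never a guess.
* **Component codes.** The model fixes component *values* for organisms,
  antigen/antibody quantities and gene names but publishes no component
  *codes* for them. The organism component uses the organism-hierarchy root
  concept as its code; the remaining sub-results use a small self-defined
  local component CodeSystem under the package's placeholder namespace.
  Profile URLs likewise live under the placeholder namespace, while value-set
  URLs that have public canonical URLs keep them verbatim.
* **Units.** Quantities use UCUM ASCII codes: MIC/MLC values in `ug/mL`
  (the micro sign only in display renderings), `mg/L` or `[arb'U]/mL`; the
  four colony-count codes each imply a unit class (`/mL`, `1`, `/g`,
  `[CFU]/mL`); `1` covers cycle thresholds and scores and `{copies}/mL`
  viral loads.
* **The immunology procedure code** is carried verbatim as `25231800`
  even though its shape is atypical; "correcting" source codes is out of
  scope for a data model.
* **No extensions.** All information maps onto core FHIR elements; a test
  scans the full synthetic corpus for `"extension"` keys.

## Serialization

`to_fhir()` / `from_fhir()` are inverse by construction: the reader rebuilds
objects through the same constructors the user calls, so a parsed resource
has re-checked every invariant. JSON output is canonical — recursively
sorted keys, unboxed scalars, full numeric precision — so serializing the
same object is byte-identical, which makes corpus-level diffing and
deterministic pipelines possible. Bundles address entries with `urn:uuid`
full URLs derived deterministically (MD5) from resource ids.
DiagnosticReport.category carries the microbiology-report coding and the
study-type coding as two codings of one CodeableConcept; emitting them as
two CodeableConcepts would also be defensible, and the choice is isolated in
one writer function should implementation-guide alignment require it.

## Validation

The validator is not a generic FHIR engine: the rules are hand-compiled from
the model's bindings into a stable catalog (`rule_catalog()`), each with a
documented id and source. All binding-derived constraints are errors;
elements outside the profiled surface are warnings (FHIR resources are
open-world and the profiles do not close them); missing *optional* elements
are never issues, reflecting the model's deliberately small mandatory core.
Issue lists are pure functions of the input, sorted by path then rule id.
The `hasMember` target-kind rule needs sibling resources to resolve
references, so it only fires when the caller supplies them (as the CLI does
per input file).

Two properties anchor the suite: every resource the writer emits from a
valid object validates with zero errors (writer/validator coherence, run
over a >1000-observation synthetic corpus), and for every catalog rule a
single-element mutation of a valid fixture triggers exactly that rule at the
mutated path (the mutation harness in the tests).

## MRGN classifier

The classifier applies the rules in a fixed order — carbapenemase ⇒ 4MRGN;
carbapenem-R and not *P. aeruginosa* ⇒ 4MRGN; then the n-of-4 count — and
records every fired rule id in `rationale`. Design points:

* **I does not count as resistant** by default: the category names
  resistance, and I denotes attainable exposure. Because local practice
  varies, `count_intermediate = TRUE` switches to the stricter reading.
* **Not-tested counts as not-resistant**, with a warning attached: an
  incomplete panel can only under-classify, and silently treating NT as R
  would invent resistance.
* The *P. aeruginosa* exception is a **descendant test** against the
  P. aeruginosa concept, so subspecies codes inherit it.
* Two resistant groups outside neonatology yield `"none"` with rationale
  `two-group-non-neonatology` — the 2MRGN label is reserved for neonatology,
  and pretending otherwise would mint categories no infection-control team
  uses.
* Species outside the Gram-negative fixture set get a warning, not an
  error: the classification is still computed, but the caller is told the
  input is outside the scheme's domain.
* The additional species-specific refinements of the full KRINKO scheme
  (e.g. a dedicated 3MRGN rule for *P. aeruginosa* based on "only one of
  four groups active") are **not implemented**; only the core rule set above
  is. This is a documented gap, not an oversight.

Correctness is established against an independently written brute-force
oracle over the exhaustive 4^4 × carbapenemase × neonatology ×
species-class grid (2048 cells), with the category totals additionally
frozen as a regression fixture, plus a monotonicity property (upgrading any
group from S to R never lowers the category).

## Synthetic data

The generator emulates the *structure* of LIS exports — one delimited row
per result, all ten kinds, culture members tied to isolates, complete
four-agent susceptibility panels with per-isolate carbapenemase and
per-patient neonatology flags, gene names and cycle thresholds in a
`key=value` flags column — and makes **no statistical realism claims**:
prevalences, resistance co-occurrence and specimen mix are uncalibrated.
Passing pipeline tests therefore demonstrates structural and semantic
correctness of the model, serializer and validator, not epidemiological
plausibility on real data. Default rates (60% positivity, 30% per-group
resistance, 5% carbapenemase, 10% neonatology) were chosen once as a
generically plausible hospital workload and are not tuned.

Determinism: one seed drives the run; each generation event derives its own
substream from a counter, so a row's content is reproducible even if event
order changes. A susceptibility event emits a complete panel (four rows), so
`n_results` counts events, not rows. The fixture snapshots themselves are
defined in code and written byte-deterministically; the toy organism
hierarchy is explicitly fictional below genus level.

## Problem sizes and numerical choices

The shipped tests use a >1000-observation corpus for the round-trip and
coherence properties, the full 2048-cell grid for the MRGN oracle
comparison, and eight random DAGs of up to 200 nodes (fixed seed) for the
descendant-closure oracle check — sizes at which every suite property is
exercised exhaustively rather than sampled. There are no floating-point
tolerances anywhere: all comparisons are exact (codes, counts, canonical
JSON bytes); quantities are serialized at full precision.

## Known limitations

* Not a general FHIR validator: no StructureDefinition interpretation, no
  FHIRPath; only the model's own rules are checked.
* No MIC-to-category translation (EUCAST/CLSI breakpoint tables are upstream
  of this package) and no Gram-positive MDRO scoring.
* No terminology-server protocol; snapshots are local files, and the bundled
  fixture is a toy.
* Molecular typing and sequencing payloads beyond qualitative molecular
  detection are out of scope.
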