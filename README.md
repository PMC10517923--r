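# microfhir

Clinical microbiology results are exchanged between hospitals in wildly
heterogeneous shapes: local test codes, free-text organisms, ad-hoc
susceptibility categories. `microfhir` implements a standard data model for
microbiology laboratory results — typed domain objects for ten observation
kinds across the culture, molecular and serology/immunology diagnostic
blocks plus the further-properties group (multidrug-resistance typing, MRGN
classification, resistance mechanisms, virulence factors) — with:

- **conformant FHIR R4 JSON serialization** (Observation, DiagnosticReport,
  Bundle), lossless in both directions, with no extensions;
- a **snapshot-based terminology engine** answering expansion and membership
  queries for extensional and intensional value sets (an ECL subset `<` /
  `<<` with subtree exclusions over SNOMED CT-like hierarchies, and
  part-based rules such as *Property = "Susc" and Method ≠ "Genotyping"* over
  LOINC-like code tables);
- a **profile validator** with a stable, documented rule catalog compiled
  from the model's terminology bindings (fixed codes, value-set membership,
  choice-type exclusivity, mandatory susceptibility-standard versions, UCUM
  unit whitelists, culture-member wiring);
- the **KRINKO MRGN classifier** for multidrug-resistant Gram-negative
  organisms (2MRGN/3MRGN/4MRGN over the four antibiotic groups
  ureidopenicillins, 3rd/4th-generation cephalosporins, carbapenems,
  fluoroquinolones, with the carbapenemase and *P. aeruginosa* special
  rules);
- a **seeded synthetic LIS generator** so the whole pipeline runs offline.

The package bundles a small fixture terminology snapshot containing every
code the model binds to, wired into a deliberately tiny toy hierarchy. Codes
in the `99xxxxxxx` / `99xxx-x` ranges are synthetic; no fixture content
should be mistaken for released SNOMED CT or LOINC terminology, which cannot
be redistributed. Real terminology releases can be plugged in as
tab-separated snapshots (`load_snapshot()`).

## The MRGN model

An isolate's susceptibility pattern over the four antibiotic groups
`G = (g_u, g_c, g_cb, g_f)`, `g ∈ {S, I, R, NT}`, is scored with
`n = |{g : g = R}|`:

- carbapenemase detected ⇒ **4MRGN**, irrespective of `G`;
- `g_cb = R` and species ∉ *P. aeruginosa* subtree ⇒ **4MRGN**;
- otherwise `n = 4` ⇒ **4MRGN**, `n = 3` ⇒ **3MRGN**, `n = 2` ⇒ **2MRGN**
  in neonatology only; anything else is not categorized.

`I` does not count as resistant by default (configurable), `NT` counts as
not-resistant with a warning.

## Worked example

```r
library(microfhir)

culture <- new_observation("culture", list(
  id = "cx-1", specimen = "Specimen/sp-1",
  result = detection_concept("detected"),
  organism = concept_ref("snomed", "112283007", "Escherichia coli (organism)")))
env <- to_fhir(culture)
cat(fhir_json(env, pretty = TRUE))
```

prints a conformant Observation (abridged):

```json
{
  "code": {"coding": [{"code": "11475-1", "display": "Microorganism identified in Specimen by Culture", "system": "http://loinc.org"}]},
  "valueCodeableConcept": {"coding": [{"code": "260373001", "display": "Detected (qualifier value)", "system": "http://snomed.info/sct"}]},
  "category": [{"coding": [{"code": "18725-2", "display": "Microbiology studies (set)", "system": "http://loinc.org"}]}],
  ...
}
```

i.e. the fixed culture-detection test code, the detected result from the
three-valued detection value set, the organism as a component, and the fixed
microbiology category. Round trip and validation:

```r
identical(from_fhir(env), culture)   # TRUE
validate_resource(env)               # 0 rows: conformant
mrgn_classify("112283007",
  c(ureidopenicillins = "R", cephalosporins = "R",
    carbapenems = "S", fluoroquinolones = "R"))
#> <MRGN 3MRGN (n resistant = 3; three-group-resistance)>
```

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/microfhir.R generate --seed 1 --out-dir demo
Rscript inst/cli/microfhir.R validate demo/observations.ndjson
Rscript inst/cli/microfhir.R expand colony-count-codes
Rscript inst/cli/microfhir.R classify-mrgn isolates.csv --out classified.csv
```

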