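{
  "resourceType": "CodeSystem",
  "id": "eucast-susceptibility",
  "url": "https://example.org/fhir/microbiology/CodeSystem/eucast-susceptibility",
  "version": "0.1.0",
  "name": "EUCASTSusceptibilityCategory",
  "title": "EUCAST susceptibility category (draft, self-defined)",
  "status": "draft",
  "content": "complete",
  "caseSensitive": true,
  "description": "Self-defined draft code system for the EUCAST antimicrobial susceptibility categories. EUCAST itself does not publish a code system and the category definitions have changed across versions, so the category is only interpretable together with the version string carried in coding.version.",
  "concept": [
    {"code": "S", "display": "Susceptible"},
    {"code": "I", "display": "Intermediate / susceptible - increased exposure"},
    {"code": "R", "display": "Resistant"}
  ]
}
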