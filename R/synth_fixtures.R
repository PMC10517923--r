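# Fixture terminology content. Codes bound by the data model are carried
# verbatim; everything in the 99xxxxxxx / 99xxx-x ranges is synthetic toy
# content (sub-root hierarchy wiring, unlisted species, extra test codes) and
# must not be mistaken for released SNOMED CT or LOINC content.

snomed_mini_df <- function() {
  r <- function(code, display, parents = "") c(code, display, parents)
  rows <- rbind(
    # organism hierarchy
    r("410607006", "Organism (organism)"),
    r("409822003", "Domain Bacteria (organism)", "410607006"),
    r("112283007", "Escherichia coli (organism)", "409822003"),
    r("56415008",  "Klebsiella pneumoniae (organism)", "409822003"),
    r("52499004",  "Pseudomonas aeruginosa (organism)", "409822003"),
    r("990001001", "Pseudomonas aeruginosa fixture subspecies (organism)", "52499004"),
    r("3092008",   "Staphylococcus aureus (organism)", "409822003"),
    r("990001005", "Acinetobacter baumannii (organism)", "409822003"),
    r("49872002",  "Virus (organism)", "410607006"),
    r("990002001", "Fixture respiratory virus (organism)", "49872002"),
    r("84676004",  "Prion (organism)", "410607006"),
    r("414561005", "Kingdom Fungi (organism)", "410607006"),
    r("990003001", "Fixture yeast (organism)", "414561005"),
    r("370570004", "Kingdom Protozoa (organism)", "410607006"),
    r("990004001", "Fixture protozoan (organism)", "370570004"),
    # the five sub-groups excluded from the organism value set
    r("990005001", "Domain Archaea (organism)", "410607006"),
    r("990005002", "Fixture archaeon (organism)", "990005001"),
    r("990006001", "Kingdom Animalia (organism)", "410607006"),
    r("990006002", "Fixture mite (organism)", "990006001"),
    r("990007001", "Kingdom Plantae (organism)", "410607006"),
    r("990007002", "Fixture plant (organism)", "990007001"),
    r("990008001", "Kingdom Viridiplantae (organism)", "410607006"),
    r("990009001", "Slime mold (organism)", "410607006"),
    # antimicrobial-resistance organism classes
    r("409793007", "Antimicrobial resistant bacteria (organism)", "410607006"),
    r("707497007", "Carbapenem resistant bacteria (organism)", "409793007"),
    r("726492000", "Carbapenem resistant Pseudomonas aeruginosa (organism)", "707497007"),
    r("115329001", "Methicillin resistant Staphylococcus aureus (organism)", "409793007"),
    r("409795000", "Antimicrobial resistant virus (organism)", "410607006"),
    r("409794001", "Antimicrobial resistant fungi (organism)", "410607006"),
    # qualifier values
    r("260373001", "Detected (qualifier value)"),
    r("260415000", "Not detected (qualifier value)"),
    r("419984006", "Inconclusive (qualifier value)"),
    r("10828004",  "Positive (qualifier value)"),
    r("260408008", "Weakly positive (qualifier value)"),
    r("260385009", "Negative (qualifier value)"),
    r("75540009",  "High (qualifier value)"),
    r("62482003",  "Low (qualifier value)"),
    r("260347006", "Present + out of ++++ (qualifier value)"),
    r("260348001", "Present ++ out of ++++ (qualifier value)"),
    r("260349009", "Present +++ out of ++++ (qualifier value)"),
    r("260350009", "Present ++++ out of ++++ (qualifier value)"),
    # procedures and observables
    r("117259009", "Microscopy (procedure)"),
    r("58586006",  "Microbial ova-parasite examination (procedure)"),
    r("117023006", "Thick film peripheral blood smear (procedure)"),
    r("408195004", "Thick film for malarial parasites (procedure)"),
    r("117024000", "Thin film peripheral blood smear method (procedure)"),
    r("67047002",  "Microbial wet smear (procedure)"),
    r("27318003",  "Potassium hydroxide preparation (procedure)"),
    r("104157003", "Light microscopy (procedure)"),
    r("73512001",  "Electron microscopic study (procedure)"),
    r("127790008", "Staining method (procedure)"),
    r("67122001",  "Acid fast stain method (procedure)", "127790008"),
    r("990010001", "Fixture differential stain method (procedure)", "127790008"),
    r("398545005", "Nucleic acid assay (procedure)"),
    r("9718006",   "Polymerase chain reaction analysis (procedure)"),
    r("25231800",  "Immunology laboratory test (procedure)"),
    r("77559007",  "Immunologic avidity, function (observable entity)"),
    r("1285113001", "Type of antimicrobial resistant organism (observable entity)"),
    r("4341000179107", "Microbiology report (record artifact)")
  )
  data.frame(code = rows[, 1], display = rows[, 2], parent_codes = rows[, 3],
             stringsAsFactors = FALSE)
}

loinc_mini_df <- function() {
  r <- function(code, display, property = "", method = "", class = "",
                component = "") c(code, display, property, method, class, component)
  rows <- rbind(
    r("11475-1", "Microorganism identified in Specimen by Culture",
      "Prid", "Culture", "MICRO", "Microorganism"),
    r("49223-1", "Colony count [#/volume] in Unspecified specimen by Visual count",
      "NCnc", "Visual count", "MICRO", "Colony count"),
    r("564-5", "Colony count [#] in Unspecified specimen by Visual count",
      "Num", "Visual count", "MICRO", "Colony count"),
    r("38436-2", "Colony count [#/mass] in Unspecified specimen by Visual count",
      "NCnt", "Visual count", "MICRO", "Colony count"),
    r("20774-6", "Colony count [Units/volume] in Unspecified specimen by Visual count",
      "ACnc", "Visual count", "MICRO", "Colony count"),
    r("18945-6", "Methicillin [Susceptibility]",
      "Susc", "", "ABXBACT", "Methicillin"),
    r("99001-1", "Piperacillin [Susceptibility]",
      "Susc", "", "ABXBACT", "Piperacillin"),
    r("99002-2", "Cefotaxime [Susceptibility]",
      "Susc", "", "ABXBACT", "Cefotaxime"),
    r("99003-3", "Meropenem [Susceptibility]",
      "Susc", "", "ABXBACT", "Meropenem"),
    r("99004-4", "Ciprofloxacin [Susceptibility]",
      "Susc", "", "ABXBACT", "Ciprofloxacin"),
    r("99005-5", "Meropenem [Susceptibility] by MIC",
      "Susc", "MIC", "ABXBACT", "Meropenem"),
    r("99006-6", "Methicillin resistance [Susceptibility] by Genotyping",
      "Susc", "Genotyping", "ABXBACT", "Methicillin resistance"),
    r("92253-4", "Microorganism identified in Isolate or Specimen by Molecular genetics method",
      "Prid", "Molecular genetics", "MICRO", "Microorganism"),
    r("88603-6", "Adenovirus Ag [Presence] in Lower respiratory specimen by Immunoassay",
      "PrThr", "Immunoassay", "MICRO", "Adenovirus Ag"),
    r("99010-0", "Cytomegalovirus IgG Ab [Presence] in Serum by Immunoassay",
      "PrThr", "Immunoassay", "MICRO", "Cytomegalovirus IgG Ab"),
    r("72421-1", "Vancomycin resistance vanB gene [Presence] by Molecular method",
      "PrThr", "Molecular", "ABXBACT", "vanB gene"),
    r("99007-7", "Carbapenemase blaKPC gene [Presence] by Molecular method",
      "PrThr", "Molecular", "ABXBACT", "blaKPC gene"),
    r("92251-8", "Microorganism gene detected [Presence] by Molecular method",
      "PrThr", "Molecular", "MICRO", "Microorganism gene"),
    r("92246-8", "Microorganism resistance mutation detected [Presence] by Molecular method",
      "PrThr", "Molecular", "MICRO", "Resistance mutation"),
    r("99008-8", "Shiga toxin 1 [Presence] in Isolate",
      "PrThr", "", "MICRO", "Shiga toxin 1"),
    r("99009-9", "Clostridioides difficile toxin B [Presence] in Stool",
      "PrThr", "", "MICRO", "Clostridioides difficile toxin B"),
    r("75371-5", "Bartlett score of Sputum Qualitative by Light microscopy",
      "Score", "Light microscopy", "MICRO", "Bartlett score"),
    r("43391-2", "Bacterial vaginosis score",
      "Score", "", "MICRO", "Nugent score"),
    r("99780-9", "Multidrug resistant Gram-negative organism classification [Type]",
      "Type", "", "MICRO", "MRGN classification"),
    r("18725-2", "Microbiology studies (set)", "-", "", "MICRO", "Microbiology studies"),
    r("92894-5", "Microbiology - bacterial studies (set)", "-", "", "MICRO", "Bacterial studies"),
    r("92893-7", "Microbiology - viral studies (set)", "-", "", "MICRO", "Viral studies"),
    r("96397-5", "Microbiology - mycobacteriology studies (set)", "-", "", "MICRO", "Mycobacteriology studies"),
    r("96398-3", "Microbiology - mycology studies (set)", "-", "", "MICRO", "Mycology studies"),
    r("92892-9", "Microbiology - parasitic studies (set)", "-", "", "MICRO", "Parasitic studies"),
    r("LA33214-0", "2MRGN", "-", "", "", "MRGN answer"),
    r("LA33215-7", "3MRGN", "-", "", "", "MRGN answer"),
    r("LA33216-5", "4MRGN", "-", "", "", "MRGN answer")
  )
  data.frame(code = rows[, 1], display = rows[, 2], property = rows[, 3],
             method = rows[, 4], class = rows[, 5], component = rows[, 6],
             stringsAsFactors = FALSE)
}

#' Write the bundled terminology fixture snapshots
#'
#' Writes `snomed_mini.tsv` (hierarchical dialect) and `loinc_mini.tsv`
#' (tabular dialect) to `out_dir`. The content is defined in code and the
#' output is byte-deterministic, so regenerating over an existing copy is a
#' no-op. These files are the snapshots every other module loads by default.
#'
#' @param out_dir Writable output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
generate_snapshot_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    snomed = file.path(out_dir, "snomed_mini.tsv"),
    loinc = file.path(out_dir, "loinc_mini.tsv")
  )
  write_tsv <- function(df, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c(paste(names(df), collapse = "\t"),
                 do.call(paste, c(unname(df), sep = "\t"))),
               con, sep = "\n", useBytes = TRUE)
  }
  write_tsv(snomed_mini_df(), paths[["snomed"]])
  write_tsv(loinc_mini_df(), paths[["loinc"]])
  invisible(paths)
}
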