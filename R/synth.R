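#' Configuration for the synthetic LIS generator
#'
#' Bundles the knobs of the synthetic laboratory-information-system export:
#' how many patients and result events, the mix over the diagnostic blocks,
#' and the rates driving detection/positivity, per-group resistance,
#' carbapenemase carriage and neonatology setting. Defaults are chosen as a
#' structurally rich general microbiology workload; the generator makes no
#' epidemiological realism claims.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param n_patients Number of synthetic patients.
#' @param n_results Number of generation events (a susceptibility event
#'   expands into a complete four-agent panel, so the table may hold more
#'   rows than events).
#' @param block_mix Named proportions over the four blocks; must sum to 1.
#' @param positivity_rate Probability a detection-style test is
#'   detected/positive.
#' @param resistance_rate Per-group probability of an R result; a single
#'   number is recycled over the four groups of [mrgn_groups()].
#' @param carbapenemase_rate Probability a bacterial isolate carries a
#'   carbapenemase.
#' @param neonatology_rate Probability a patient is a neonatology patient.
#' @param fault_rate Probability a row is deliberately corrupted (missing
#'   susceptibility version, wrong result value set) for validator testing;
#'   corrupted rows are marked in the `flags` column.
#' @return Object of class `mf_synth_config`.
#' @export
synth_config <- function(seed = 1L, n_patients = 20L, n_results = 100L,
                         block_mix = c(culture = 0.45, molecular = 0.25,
                                       serology = 0.15,
                                       `further-properties` = 0.15),
                         positivity_rate = 0.6,
                         resistance_rate = 0.3,
                         carbapenemase_rate = 0.05,
                         neonatology_rate = 0.1,
                         fault_rate = 0) {
  stopifnot(length(block_mix) == 4L,
            setequal(names(block_mix), model_blocks()))
  if (abs(sum(block_mix) - 1) > 1e-9) {
    stop("block_mix proportions must sum to 1", call. = FALSE)
  }
  if (length(resistance_rate) == 1L) {
    resistance_rate <- stats::setNames(rep(resistance_rate, 4L), mrgn_groups())
  }
  stopifnot(setequal(names(resistance_rate), mrgn_groups()))
  probs <- c(positivity_rate, resistance_rate, carbapenemase_rate,
             neonatology_rate, fault_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 n_results = as.integer(n_results),
                 block_mix = block_mix[model_blocks()],
                 positivity_rate = positivity_rate,
                 resistance_rate = resistance_rate[mrgn_groups()],
                 carbapenemase_rate = carbapenemase_rate,
                 neonatology_rate = neonatology_rate,
                 fault_rate = fault_rate),
            class = "mf_synth_config")
}

LIS_COLUMNS <- c("patient_id", "isolate_id", "row_id", "block", "kind",
                 "test_code", "test_system", "result_code_or_value", "unit",
                 "interpretation", "scheme", "scheme_version", "method_code",
                 "organism_code", "flags")

GN_SPECIES <- c("112283007", "56415008", "52499004", "990001005")
CULTURE_SPECIES <- c(GN_SPECIES, "3092008")
ANY_ORGANISM <- c(CULTURE_SPECIES, "990002001", "990003001", "990004001")
GROUP_AGENTS <- c(ureidopenicillins = "99001-1", cephalosporins = "99002-2",
                  carbapenems = "99003-3", fluoroquinolones = "99004-4")
MICROSCOPY_METHODS <- c("58586006", "117023006", "408195004", "117024000",
                        "67047002", "27318003", "104157003", "73512001",
                        "67122001", "990010001")

# One derived substream per event keeps rows reproducible under reordering.
event_seed <- function(seed, i) (seed %% 65536L) * 32749L + i * 7L

encode_flags <- function(...) {
  kv <- list(...)
  kv <- kv[!vapply(kv, is.null, logical(1))]
  if (!length(kv)) return("")
  paste(paste0(names(kv), "=", unlist(kv)), collapse = ";")
}

parse_flags <- function(flags) {
  if (is.na(flags) || !nzchar(flags)) return(list())
  parts <- strsplit(flags, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, character(1), 1))
}

#' Generate a synthetic LIS result table
#'
#' Produces a delimited-text-style table of microbiology results spanning all
#' four diagnostic blocks, deterministically for a fixed seed. The first ten
#' events cover each observation kind once (so every kind is exercised from
#' `n_results >= 10`); subsequent events follow `block_mix`. Colony-count and
#' susceptibility events attach to a previously detected bacterial isolate
#' (falling back to a new culture when none exists yet). Susceptibility
#' events emit a complete four-agent panel with per-isolate carbapenemase
#' status and per-patient neonatology setting recorded in `flags`; gene names
#' and PCR cycle thresholds travel in `flags` too (`key=value;...`).
#'
#' @param config An [synth_config()].
#' @return `data.frame` with the documented LIS columns, plus the config as
#'   attribute `config`.
#' @export
generate_lab_table <- function(config) {
  stopifnot(inherits(config, "mf_synth_config"))
  rows <- list()
  pool <- list()   # detected bacterial isolates: list(isolate, patient, species)
  n_iso <- 0L
  add <- function(...) {
    row <- list(...)
    full <- stats::setNames(as.list(rep("", length(LIS_COLUMNS))), LIS_COLUMNS)
    full[names(row)] <- lapply(row, as.character)
    rows[[length(rows) + 1L]] <<- full
  }
  forced <- c("culture", "colony_count", "susceptibility", "microscopy",
              "molecular", "serology", "mdro_type", "mrgn",
              "resistance_mechanism", "virulence")
  kind_block <- stats::setNames(observation_kinds()$block,
                                observation_kinds()$kind)
  for (i in seq_len(config$n_results)) {
    set.seed(event_seed(config$seed, i))
    patient <- sprintf("P%03d", sample.int(config$n_patients, 1L))
    neo <- stats::runif(1) < config$neonatology_rate
    kind <- if (i <= length(forced)) forced[i] else {
      block <- sample(names(config$block_mix), 1L, prob = config$block_mix)
      switch(block,
        culture = sample(c("culture", "colony_count", "susceptibility",
                           "microscopy"), 1L, prob = c(.45, .2, .2, .15)),
        molecular = "molecular",
        serology = "serology",
        `further-properties` = sample(c("mdro_type", "mrgn",
                                        "resistance_mechanism", "virulence"), 1L)
      )
    }
    if (kind %in% c("colony_count", "susceptibility") && !length(pool)) {
      kind <- "culture"
    }
    rid <- sprintf("R%04d", length(rows) + 1L)
    fault <- config$fault_rate > 0 && stats::runif(1) < config$fault_rate
    block <- kind_block[[kind]]
    if (kind == "culture") {
      n_iso <- n_iso + 1L
      iso <- sprintf("ISO%04d", n_iso)
      detected <- stats::runif(1) < config$positivity_rate
      result <- if (detected) "260373001" else {
        if (stats::runif(1) < 0.9) "260415000" else "419984006"
      }
      species <- if (detected) sample(CULTURE_SPECIES, 1L) else ""
      if (fault) result <- "10828004"  # positivity code in a detection slot
      add(patient_id = patient, isolate_id = iso, row_id = rid, block = block,
          kind = kind, test_code = "11475-1", test_system = "loinc",
          result_code_or_value = result, organism_code = species,
          flags = encode_flags(fault = if (fault) "wrong-result-vs"))
      if (detected && !fault && nzchar(species)) {
        pool[[length(pool) + 1L]] <- list(isolate = iso, patient = patient,
                                          species = species)
      }
    } else if (kind == "colony_count") {
      host <- pool[[sample.int(length(pool), 1L)]]
      code <- sample(c("49223-1", "564-5", "38436-2", "20774-6"), 1L)
      if (stats::runif(1) < 0.3) {
        semi <- sample(c("260347006", "260348001", "260349009", "260350009"), 1L)
        add(patient_id = host$patient, isolate_id = host$isolate, row_id = rid,
            block = block, kind = kind, test_code = code,
            test_system = "loinc", result_code_or_value = semi)
      } else {
        add(patient_id = host$patient, isolate_id = host$isolate, row_id = rid,
            block = block, kind = kind, test_code = code,
            test_system = "loinc",
            result_code_or_value = format(10^sample(3:6, 1L),
                                          scientific = FALSE),
            unit = ucum_units(code))
      }
    } else if (kind == "susceptibility") {
      host <- pool[[sample.int(length(pool), 1L)]]
      scheme <- sample(c("EUCAST", "CLSI"), 1L)
      version <- if (scheme == "EUCAST") "13.0" else "M100-Ed33"
      carb <- stats::runif(1) < config$carbapenemase_rate
      for (g in mrgn_groups()) {
        interp <- if (stats::runif(1) < config$resistance_rate[[g]]) "R" else {
          if (stats::runif(1) < 0.1) "I" else "S"
        }
        rid_g <- sprintf("R%04d", length(rows) + 1L)
        fault_g <- fault && g == "carbapenems"
        add(patient_id = host$patient, isolate_id = host$isolate,
            row_id = rid_g, block = block, kind = kind,
            test_code = GROUP_AGENTS[[g]], test_system = "loinc",
            interpretation = interp, scheme = scheme,
            scheme_version = if (fault_g) "" else version,
            organism_code = host$species,
            flags = encode_flags(
              group = g,
              mic = if (stats::runif(1) < 0.5) {
                format(sample(c(0.25, 0.5, 1, 2, 4, 8, 16), 1L),
                       scientific = FALSE)
              },
              carbapenemase = tolower(carb), neonatology = tolower(neo),
              fault = if (fault_g) "missing-version"))
      }
    } else if (kind == "microscopy") {
      detected <- stats::runif(1) < config$positivity_rate
      result <- if (detected) "260373001" else {
        if (stats::runif(1) < 0.9) "260415000" else "419984006"
      }
      add(patient_id = patient, row_id = rid, block = block, kind = kind,
          test_code = "117259009", test_system = "snomed",
          result_code_or_value = result,
          method_code = sample(MICROSCOPY_METHODS, 1L),
          organism_code = if (detected) sample(CULTURE_SPECIES, 1L) else "")
    } else if (kind == "molecular") {
      positive <- stats::runif(1) < config$positivity_rate
      result <- if (positive) {
        if (stats::runif(1) < 0.15) "260408008" else "10828004"
      } else {
        if (stats::runif(1) < 0.9) "260385009" else "419984006"
      }
      if (fault) result <- "260373001"  # detection code in a positivity slot
      add(patient_id = patient, row_id = rid, block = block, kind = kind,
          test_code = "92253-4", test_system = "loinc",
          result_code_or_value = result,
          organism_code = if (positive) sample(ANY_ORGANISM, 1L) else "",
          flags = encode_flags(
            ct = if (positive) sample(18:35, 1L),
            fault = if (fault) "wrong-result-vs"))
    } else if (kind == "serology") {
      positive <- stats::runif(1) < config$positivity_rate
      result <- if (positive) "10828004" else {
        if (stats::runif(1) < 0.9) "260385009" else "419984006"
      }
      test <- sample(c("25231800", "88603-6", "99010-0"), 1L)
      add(patient_id = patient, row_id = rid, block = block, kind = kind,
          test_code = test,
          test_system = if (test == "25231800") "snomed" else "loinc",
          result_code_or_value = result)
    } else if (kind == "mdro_type") {
      add(patient_id = patient, row_id = rid, block = block, kind = kind,
          test_code = "1285113001", test_system = "snomed",
          result_code_or_value = sample(c("707497007", "726492000",
                                          "115329001"), 1L))
    } else if (kind == "mrgn") {
      add(patient_id = patient, row_id = rid, block = block, kind = kind,
          test_code = "99780-9", test_system = "loinc",
          result_code_or_value = sample(c("LA33214-0", "LA33215-7",
                                          "LA33216-5"), 1L,
                                        prob = c(.15, .45, .4)))
    } else if (kind == "resistance_mechanism") {
      positive <- stats::runif(1) < config$positivity_rate
      test <- sample(c("72421-1", "99007-7", "92251-8"), 1L)
      add(patient_id = patient, row_id = rid, block = block, kind = kind,
          test_code = test, test_system = "loinc",
          result_code_or_value = if (positive) "10828004" else "260385009",
          flags = if (test == "92251-8") {
            encode_flags(gene = "blaKPC-2", gene_source = "NCBI",
                         gene_id = "NG_049253")
          } else "")
    } else if (kind == "virulence") {
      detected <- stats::runif(1) < config$positivity_rate
      add(patient_id = patient, row_id = rid, block = block, kind = kind,
          test_code = sample(c("99008-8", "99009-9"), 1L),
          test_system = "loinc",
          result_code_or_value = if (detected) "260373001" else "260415000")
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "config") <- config
  out
}

#' Convert a LIS table into observations
#'
#' Builds one observation per row of a table in the documented LIS schema and
#' wires colony-count / susceptibility rows to their culture row (matched on
#' `isolate_id`) as culture members. Rows are ingested leniently
#' (`validate = FALSE`), so deliberately corrupted rows still yield
#' observations that the validator can flag; rows that cannot be interpreted
#' at all (unknown kind or test code, member row without a culture row) are
#' collected as row-level errors, never raised.
#'
#' @param table Data frame in the LIS schema (see [generate_lab_table()]).
#' @param snapshots,catalog Terminology context.
#' @return List with `observations` (list of `mf_observation`) and `errors`
#'   (`data.frame` with `row_id`, `message`).
#' @export
table_to_observations <- function(table, snapshots = cached_snapshots(),
                                  catalog = default_catalog()) {
  errors <- list()
  obs <- list()
  culture_by_iso <- list()
  blank <- function(x) is.na(x) || !nzchar(x)
  for (i in seq_len(nrow(table))) {
    row <- table[i, ]
    flags <- parse_flags(row$flags)
    payload <- list(id = row$row_id)
    kind <- row$kind
    ok <- TRUE
    fail <- function(msg) {
      errors[[length(errors) + 1L]] <<-
        data.frame(row_id = row$row_id, message = msg,
                   stringsAsFactors = FALSE)
      ok <<- FALSE
    }
    if (!kind %in% observation_kinds()$kind) {
      fail(paste0("unknown observation kind '", kind, "'"))
      next
    }
    sn <- function(code, display = NULL) concept_ref("snomed", code, display)
    ln <- function(code, display = NULL) concept_ref("loinc", code, display)
    test_concept <- function() {
      if (identical(row$test_system, "snomed")) sn(row$test_code)
      else ln(row$test_code)
    }
    payload <- switch(kind,
      culture = {
        p <- list(result = sn(row$result_code_or_value))
        if (!blank(row$organism_code)) p$organism <- sn(row$organism_code)
        p
      },
      colony_count = {
        p <- list(code = ln(row$test_code))
        # numeric results always carry a unit; semiquantitative codes do not
        if (!blank(row$unit)) {
          p$quantity <- quantity(as.numeric(row$result_code_or_value),
                                 row$unit)
        } else {
          p$semiquant <- sn(row$result_code_or_value)
        }
        p
      },
      susceptibility = {
        p <- list(agent = ln(row$test_code),
                  interpretation = row$interpretation,
                  scheme = row$scheme, scheme_version = row$scheme_version)
        if (!is.null(flags$mic)) {
          p$mic <- quantity(as.numeric(flags$mic), "ug/mL")
        }
        p
      },
      microscopy = {
        p <- list(result = sn(row$result_code_or_value),
                  method = sn(row$method_code))
        if (!blank(row$organism_code)) p$organism <- sn(row$organism_code)
        p
      },
      molecular = {
        p <- list(result = sn(row$result_code_or_value))
        if (!blank(row$organism_code)) p$organism <- sn(row$organism_code)
        if (!is.null(flags$ct)) {
          p$assay <- list(list(
            code = sn("9718006", "Polymerase chain reaction analysis (procedure)"),
            value = quantity(as.numeric(flags$ct), "1")))
        }
        p
      },
      serology = list(test = test_concept(),
                      result = sn(row$result_code_or_value)),
      mdro_type = list(value = sn(row$result_code_or_value)),
      mrgn = list(value = ln(row$result_code_or_value)),
      resistance_mechanism = {
        p <- list(test = ln(row$test_code),
                  result = sn(row$result_code_or_value))
        if (!is.null(flags$gene)) {
          p$gene <- list(name = flags$gene,
                         source = flags$gene_source %||% "NCBI",
                         identifier = flags$gene_id %||% flags$gene)
        }
        p
      },
      virulence = list(test = ln(row$test_code),
                       result = sn(row$result_code_or_value))
    )
    if (!ok) next
    payload$id <- row$row_id
    o <- tryCatch(
      new_observation(kind, payload, snapshots, catalog, validate = FALSE),
      error = function(e) {
        fail(conditionMessage(e))
        NULL
      })
    if (is.null(o)) next
    obs[[length(obs) + 1L]] <- o
    if (kind == "culture" && !blank(row$isolate_id)) {
      culture_by_iso[[row$isolate_id]] <- length(obs)
    }
    if (kind %in% c("colony_count", "susceptibility") &&
        !blank(row$isolate_id)) {
      idx <- culture_by_iso[[row$isolate_id]]
      if (is.null(idx)) {
        fail(paste0("isolate '", row$isolate_id,
                    "' has no preceding culture row"))
      } else if (identical(obs[[idx]]$result$code,
                           DETECTION_CODES[["detected"]])) {
        obs[[idx]] <- link_culture_children(obs[[idx]], row$row_id)
      }
    }
  }
  list(observations = obs,
       errors = if (length(errors)) {
         do.call(rbind, errors)
       } else {
         data.frame(row_id = character(0), message = character(0),
                    stringsAsFactors = FALSE)
       })
}
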