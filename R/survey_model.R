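#' Half-up decimal rounding
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used for all display values in ethnobotanical index tables
#' (base R's `round()` rounds half to even). A small epsilon absorbs binary
#' representation error so that e.g. 74/80 rounds to 0.93.
#'
#' @param x Numeric vector.
#' @param digits Non-negative integer number of decimal places.
#' @return Numeric vector of the same length.
#' @examples
#' round_half_up(0.925, 2) # 0.93
#' round_half_up(0.225, 2) # 0.23
#' @export
round_half_up <- function(x, digits = 2) {
  stopifnot(is.numeric(x), digits >= 0)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Analysis configuration
#'
#' Bundles the tunable constants shared across pipeline stages: display
#' rounding, the value reported for the degenerate Fic denominator, the
#' association-rule thresholds, and the seed used by any stochastic step.
#'
#' @param rounding_digits Decimal places for display values (half-up).
#' @param fic_degenerate_value Value reported for a category with a single
#'   use report, where the Fic denominator `Nur - 1` vanishes.
#' @param min_support Minimum number of co-citing informants for a rule.
#' @param min_confidence Minimum conditional probability for a rule.
#' @param seed Integer seed.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(rounding_digits = 2, fic_degenerate_value = 0,
                            min_support = 2, min_confidence = 0.5, seed = 1L) {
  stopifnot(rounding_digits >= 0, min_support >= 0, min_confidence >= 0)
  structure(
    list(rounding_digits = as.integer(rounding_digits),
         fic_degenerate_value = fic_degenerate_value,
         min_support = as.integer(min_support),
         min_confidence = min_confidence,
         seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from YAML or JSON
#'
#' Reads the fields of [analysis_config()] from a config file; missing
#' fields keep their defaults, unknown fields are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing config file: %s", path), call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(analysis_config, vals)
}

#' Canonicalize a scientific plant name
#'
#' Reduces a decorated name to the authority-stripped binomial used as the
#' matching key throughout the package: markup (`*`, `_`) is removed,
#' whitespace collapsed, the genus capitalized and the epithet lower-cased,
#' and the author citation dropped. Infraspecific ranks (`var.`, `subsp.`,
#' `ssp.`, `f.`) are preserved together with their epithet. The operation is
#' idempotent, so canonical names pass through unchanged.
#'
#' @param raw Character vector of raw names.
#' @return Character vector of canonical binomials.
#' @examples
#' canonicalize_name("*Justicia procumbens* L.")
#' canonicalize_name("Raphanus raphanistrum subsp. sativus (L.) Domin.")
#' @export
canonicalize_name <- function(raw) {
  stopifnot(is.character(raw))
  vapply(raw, canonicalize_one, character(1), USE.NAMES = FALSE)
}

canonicalize_one <- function(x) {
  x <- gsub("[*_]", "", x)
  x <- stringr::str_squish(x)
  if (!nzchar(x)) {
    stop("canonicalize_name(): empty or whitespace-only name", call. = FALSE)
  }
  tokens <- strsplit(x, " ", fixed = TRUE)[[1]]
  genus <- paste0(toupper(substr(tokens[1], 1, 1)),
                  tolower(substr(tokens[1], 2, nchar(tokens[1]))))
  genus <- gsub("[^A-Za-z-]", "", genus)
  if (length(tokens) < 2) {
    return(genus)
  }
  epithet <- gsub("[^a-z-]", "", tolower(tokens[2]))
  out <- paste(genus, epithet)
  # keep one infraspecific rank + epithet if present after the binomial
  rank_markers <- c("var.", "subsp.", "ssp.", "f.")
  if (length(tokens) > 3) {
    pos <- which(tolower(tokens) %in% rank_markers)
    pos <- pos[pos >= 3 & pos < length(tokens)]
    if (length(pos) > 0) {
      i <- pos[1]
      rank <- tolower(tokens[i])
      if (rank == "ssp.") rank <- "subsp."
      infra <- gsub("[^a-z-]", "", tolower(tokens[i + 1]))
      if (nzchar(infra)) out <- paste(out, rank, infra)
    }
  }
  out
}

#' Construct a survey dataset
#'
#' The central container for one ethnobotanical survey: an informant table
#' (demographics plus inclusion flag), a species table (taxonomy, local
#' names, voucher, source, optional red-list status), a long-format
#' use-report table where one row is one use report — one informant citing
#' one species for one ailment, the atomic unit of both the use-value
#' numerator Ui and the consensus numerator Nur — and an optional ailment map
#' assigning each free-text ailment to an ICPC category.
#'
#' `n_informants`, the denominator N of UV and RFC, is the number of
#' *included* informants; reports from excluded informants are a validation
#' error.
#'
#' @param informants Tibble with columns `informant_id`, `gender`,
#'   `age_band`, `township`, `education`, `knowledge_sources`
#'   (";"-separated), `included` (logical).
#' @param species Tibble with columns `species_id`, `canonical_name`,
#'   `family`, `local_names`, `voucher_id`, `source`, `red_list_status`.
#' @param reports Tibble with columns `informant_id`, `species_id`,
#'   `ailment_text`, `part`, `preparation`, `route`.
#' @param ailment_map Optional tibble with columns `ailment_text`,
#'   `icpc_category`.
#' @param check If `TRUE` (default) hard structural problems (duplicate ids,
#'   dangling foreign keys, reports from excluded informants) raise an error.
#' @return An object of class `survey_dataset`.
#' @export
survey_dataset <- function(informants, species, reports, ailment_map = NULL,
                           check = TRUE) {
  informants <- tibble::as_tibble(informants)
  species <- tibble::as_tibble(species)
  reports <- tibble::as_tibble(reports)
  if (!is.null(ailment_map)) ailment_map <- tibble::as_tibble(ailment_map)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      stop(sprintf("%s table missing column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  need(informants, c("informant_id", "included"), "informants")
  need(species, c("species_id", "canonical_name"), "species")
  need(reports, c("informant_id", "species_id", "ailment_text"), "reports")

  ds <- structure(
    list(informants = informants, species = species, reports = reports,
         ailment_map = ailment_map,
         n_informants = sum(informants$included)),
    class = "survey_dataset"
  )
  if (check) {
    issues <- validate_survey(ds)
    hard <- issues[issues$severity == "error", , drop = FALSE]
    if (nrow(hard) > 0) {
      stop(paste0("invalid survey dataset:\n",
                  paste0("  - ", hard$message, collapse = "\n")),
           call. = FALSE)
    }
  }
  ds
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf(
    "<survey_dataset> %d informants (%d included), %d species, %d use reports\n",
    nrow(x$informants), x$n_informants, nrow(x$species), nrow(x$reports)))
  if (!is.null(x$ailment_map)) {
    cat(sprintf("  ailment map: %d ailments -> %d ICPC categories\n",
                nrow(x$ailment_map), dplyr::n_distinct(x$ailment_map$icpc_category)))
  }
  invisible(x)
}

#' Validate a survey dataset
#'
#' Runs every structural and vocabulary check and returns the findings as
#' data rather than raising: one row per issue with its type, the table and
#' row concerned, a severity (`error` for referential problems that make
#' index computation meaningless, `warning` for vocabulary deviations), and
#' a human-readable message. A clean dataset yields a zero-row tibble.
#'
#' @param ds A `survey_dataset`.
#' @return A tibble with columns `issue`, `table`, `row`, `severity`,
#'   `message`.
#' @export
validate_survey <- function(ds) {
  stopifnot(inherits(ds, "survey_dataset"))
  issues <- list()
  add <- function(issue, table, row, severity, message) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      issue = issue, table = table, row = as.integer(row),
      severity = severity, message = message)
  }

  dup <- which(duplicated(ds$informants$informant_id))
  for (i in dup) {
    add("duplicate-id", "informants", i, "error",
        sprintf("informants row %d: duplicate informant_id '%s'",
                i, ds$informants$informant_id[i]))
  }
  dup <- which(duplicated(ds$species$species_id))
  for (i in dup) {
    add("duplicate-id", "species", i, "error",
        sprintf("species row %d: duplicate species_id '%s'",
                i, ds$species$species_id[i]))
  }
  empty <- which(!nzchar(trimws(ds$species$canonical_name)))
  for (i in empty) {
    add("empty-name", "species", i, "error",
        sprintf("species row %d: empty canonical_name", i))
  }

  if (nrow(ds$reports) > 0) {
    bad <- which(!(ds$reports$informant_id %in% ds$informants$informant_id))
    for (i in bad) {
      add("dangling-foreign-key", "reports", i, "error",
          sprintf("reports row %d: unknown informant_id '%s'",
                  i, ds$reports$informant_id[i]))
    }
    bad <- which(!(ds$reports$species_id %in% ds$species$species_id))
    for (i in bad) {
      add("dangling-foreign-key", "reports", i, "error",
          sprintf("reports row %d: unknown species_id '%s'",
                  i, ds$reports$species_id[i]))
    }
    excluded <- ds$informants$informant_id[!ds$informants$included]
    bad <- which(ds$reports$informant_id %in% excluded)
    for (i in bad) {
      add("excluded-informant-report", "reports", i, "error",
          sprintf("reports row %d: informant '%s' is excluded but has reports",
                  i, ds$reports$informant_id[i]))
    }

    check_vocab <- function(col, vocab) {
      if (!col %in% names(ds$reports)) return()
      vals <- ds$reports[[col]]
      ok <- vapply(split_multi(vals), function(v) all(v %in% vocab) || all(is.na(v)),
                   logical(1))
      for (i in which(!ok & !is.na(vals))) {
        add("vocabulary", "reports", i, "warning",
            sprintf("reports row %d: %s '%s' outside vocabulary",
                    i, col, vals[i]))
      }
    }
    check_vocab("part", part_vocabulary())
    check_vocab("preparation", preparation_vocabulary())
    check_vocab("route", route_vocabulary())

    if (!is.null(ds$ailment_map)) {
      unmapped <- which(!(ds$reports$ailment_text %in% ds$ailment_map$ailment_text))
      for (i in unmapped) {
        add("unmapped-ailment", "reports", i, "error",
            sprintf("reports row %d: ailment '%s' missing from ailment map",
                    i, ds$reports$ailment_text[i]))
      }
    }
  }

  if (!is.null(ds$ailment_map)) {
    bad <- which(!(ds$ailment_map$icpc_category %in% icpc_categories()))
    for (i in bad) {
      add("vocabulary", "ailment_map", i, "warning",
          sprintf("ailment_map row %d: unknown ICPC category '%s'",
                  i, ds$ailment_map$icpc_category[i]))
    }
  }

  if (length(issues) == 0) {
    return(tibble::tibble(issue = character(), table = character(),
                          row = integer(), severity = character(),
                          message = character()))
  }
  dplyr::bind_rows(issues)
}

survey_csv_cols <- list(
  informants = readr::cols(
    informant_id = readr::col_character(), gender = readr::col_character(),
    age_band = readr::col_character(), township = readr::col_character(),
    education = readr::col_character(),
    knowledge_sources = readr::col_character(),
    included = readr::col_logical()),
  species = readr::cols(
    species_id = readr::col_character(),
    canonical_name = readr::col_character(), family = readr::col_character(),
    local_names = readr::col_character(), voucher_id = readr::col_character(),
    source = readr::col_character(), red_list_status = readr::col_character()),
  use_reports = readr::cols(
    informant_id = readr::col_character(),
    species_id = readr::col_character(),
    ailment_text = readr::col_character(), part = readr::col_character(),
    preparation = readr::col_character(), route = readr::col_character()),
  ailment_map = readr::cols(
    ailment_text = readr::col_character(),
    icpc_category = readr::col_character())
)

#' Load a survey from a directory of CSV files
#'
#' Reads `informants.csv`, `species.csv` and `use_reports.csv` (plus
#' `ailment_map.csv` when present) from `dir`, canonicalizes all species
#' names, and returns a validated [survey_dataset()]. Files are UTF-8
#' comma-separated with ";" as the inner separator of multi-valued cells.
#' Structural problems (missing file, dangling key, unmapped ailment) raise
#' errors that name the offending row.
#'
#' @param dir Directory containing the survey CSV files.
#' @param config An [analysis_config()] (reserved for rounding/seed options;
#'   loading itself is deterministic).
#' @return A `survey_dataset`.
#' @export
load_survey <- function(dir, config = analysis_config()) {
  read_one <- function(fname, spec, required = TRUE) {
    path <- file.path(dir, fname)
    if (!file.exists(path)) {
      if (required) stop(sprintf("missing survey file: %s", path), call. = FALSE)
      return(NULL)
    }
    # empty string is the missing marker: "NA" is a genuine red-list token
    readr::read_csv(path, col_types = spec, progress = FALSE, na = "",
                    locale = readr::locale(encoding = "UTF-8"))
  }
  informants <- read_one("informants.csv", survey_csv_cols$informants)
  species <- read_one("species.csv", survey_csv_cols$species)
  reports <- read_one("use_reports.csv", survey_csv_cols$use_reports)
  ailment_map <- read_one("ailment_map.csv", survey_csv_cols$ailment_map,
                          required = FALSE)
  species$canonical_name <- canonicalize_name(species$canonical_name)
  survey_dataset(informants, species, reports, ailment_map = ailment_map)
}

#' Write a survey dataset to CSV files
#'
#' Inverse of [load_survey()]: writes the standard schema
#' (`informants.csv`, `species.csv`, `use_reports.csv`, and
#' `ailment_map.csv` if the dataset carries a map) so that loading the
#' directory reproduces the dataset field for field.
#'
#' @param ds A `survey_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(ds, dir) {
  stopifnot(inherits(ds, "survey_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, fname) {
    readr::write_csv(df, file.path(dir, fname), na = "", progress = FALSE)
  }
  wr(ds$informants, "informants.csv")
  wr(ds$species, "species.csv")
  wr(ds$reports, "use_reports.csv")
  if (!is.null(ds$ailment_map)) wr(ds$ailment_map, "ailment_map.csv")
  invisible(dir)
}
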