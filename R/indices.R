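#' Per-species cultural-importance indices
#'
#' For each species computes the four standard citation indices over the
#' included-informant denominator N:
#' \describe{
#'   \item{sum_ui}{total number of use reports (one informant citing the
#'     species for one ailment is one report, so an informant citing a
#'     species for two ailments contributes 2)}
#'   \item{uv}{use value, `sum_ui / N` — mean use reports per informant}
#'   \item{fc}{frequency of citation — number of distinct citing informants}
#'   \item{rfc}{relative frequency of citation, `fc / N`}
#' }
#' Raw (unrounded) values are kept alongside the half-up display values.
#' Rows are ordered by `uv_raw` descending, ties broken by `fc` then
#' `canonical_name`, mirroring the published index tables.
#'
#' @param ds A [survey_dataset()].
#' @param include_uncited If `TRUE`, species never cited appear with all-zero
#'   indices; by default only cited species are returned.
#' @param digits Display rounding (half-up decimal places).
#' @return A tibble with one row per species: `species_id`,
#'   `canonical_name`, `family`, `sum_ui`, `uv_raw`, `uv`, `fc`, `rfc_raw`,
#'   `rfc`.
#' @export
compute_species_indices <- function(ds, include_uncited = FALSE, digits = 2) {
  stopifnot(inherits(ds, "survey_dataset"))
  n <- ds$n_informants
  if (n <= 0) stop("no included informants: index denominator N is zero", call. = FALSE)

  # base tabulation keeps this hot path fast on thousands of small datasets
  rep_sp <- ds$reports$species_id
  sum_ui_tab <- table(rep_sp)
  first_pair <- !duplicated(paste(ds$reports$informant_id, rep_sp, sep = "\r"))
  fc_tab <- table(rep_sp[first_pair])

  sp_cols <- intersect(c("species_id", "canonical_name", "family"), names(ds$species))
  out <- ds$species[, sp_cols]
  lookup <- function(tab) {
    v <- as.integer(tab[match(out$species_id, names(tab))])
    v[is.na(v)] <- 0L
    v
  }
  out$sum_ui <- lookup(sum_ui_tab)
  out$fc <- lookup(fc_tab)
  if (!include_uncited) {
    out <- out[out$sum_ui > 0, , drop = FALSE]
  }
  out$uv_raw <- out$sum_ui / n
  out$uv <- round_half_up(out$uv_raw, digits)
  out$rfc_raw <- out$fc / n
  out$rfc <- round_half_up(out$rfc_raw, digits)
  out <- out[order(-out$uv_raw, -out$fc, out$canonical_name), , drop = FALSE]
  dplyr::relocate(out, "uv_raw", "uv", .after = "sum_ui")
}

#' Factor of informant consensus per ICPC category
#'
#' Computes, for every ICPC category with at least one mapped use report,
#' `Nur` (number of use reports in the category), `Nt` (number of distinct
#' taxa cited for the category), and the factor of informant consensus
#'
#' \deqn{F_{ic} = \frac{N_{ur} - N_t}{N_{ur} - 1}}
#'
#' Fic approaches 1 when many reports converge on few taxa (strong
#' consensus) and 0 when nearly every report names a different taxon. A
#' category with a single report has a vanishing denominator and is reported
#' as `fic_degenerate_value` (0 by convention: one report carries no
#' evidence of agreement).
#'
#' @param ds A [survey_dataset()].
#' @param ailment_map Tibble mapping `ailment_text` to `icpc_category`;
#'   defaults to the map carried by the dataset. Every reported ailment must
#'   be mapped.
#' @param fic_degenerate_value Value reported when `Nur <= 1`.
#' @param digits Display rounding.
#' @return A tibble with columns `icpc_category`, `nur`, `nt`, `fic_raw`,
#'   `fic`, ordered by `fic_raw` then `nur` descending.
#' @export
compute_fic <- function(ds, ailment_map = ds$ailment_map,
                        fic_degenerate_value = 0, digits = 2) {
  stopifnot(inherits(ds, "survey_dataset"))
  if (is.null(ailment_map)) {
    stop("compute_fic() needs an ailment map (ailment_text -> icpc_category)",
         call. = FALSE)
  }
  if (nrow(ds$reports) == 0) {
    return(tibble::tibble(icpc_category = character(), nur = integer(),
                          nt = integer(), fic_raw = numeric(), fic = numeric()))
  }
  cat <- ailment_map$icpc_category[match(ds$reports$ailment_text,
                                         ailment_map$ailment_text)]
  if (anyNA(cat)) {
    unmapped <- unique(ds$reports$ailment_text[is.na(cat)])
    stop(sprintf("unmapped ailment text(s): %s",
                 paste(utils::head(unmapped, 5), collapse = "; ")), call. = FALSE)
  }
  nur_tab <- table(cat)
  first_taxon <- !duplicated(paste(cat, ds$reports$species_id, sep = "\r"))
  nt_tab <- table(cat[first_taxon])
  cats <- names(nur_tab)
  nur <- as.integer(nur_tab)
  nt <- as.integer(nt_tab[match(cats, names(nt_tab))])
  fic_raw <- ifelse(nur > 1, (nur - nt) / (nur - 1), fic_degenerate_value)
  out <- tibble::tibble(icpc_category = cats, nur = nur, nt = nt,
                        fic_raw = fic_raw,
                        fic = round_half_up(fic_raw, digits))
  out[order(-out$fic_raw, -out$nur, out$icpc_category), , drop = FALSE]
}

#' Frequency tabulations of survey attributes
#'
#' Reproduces the survey's descriptive tabulations with their counting
#' conventions:
#' * `part`, `preparation`, `route` — per-species multi-count: every
#'   *distinct* value a species was recorded with counts once, so a species
#'   used both whole and as leaves contributes 2 to the denominator.
#'   Multi-valued cells (";"-separated) are split first.
#' * `family` — one count per species.
#' * `knowledge_source` — per-informant multi-count over included
#'   informants (an informant naming two sources contributes 2).
#'
#' @param ds A [survey_dataset()].
#' @param attribute One of `"part"`, `"preparation"`, `"route"`,
#'   `"family"`, `"knowledge_source"`.
#' @param digits Display rounding for percentages.
#' @return A tibble `value`, `count`, `pct` ordered by count descending,
#'   with the denominator attached as attribute `"denominator"` (counts sum
#'   to it exactly).
#' @export
tabulate_attribute <- function(ds, attribute, digits = 2) {
  stopifnot(inherits(ds, "survey_dataset"))
  attribute <- match.arg(attribute,
                         c("part", "preparation", "route", "family",
                           "knowledge_source"))
  if (attribute %in% c("part", "preparation", "route")) {
    pairs <- ds$reports |>
      dplyr::select("species_id", value = dplyr::all_of(attribute)) |>
      dplyr::filter(!is.na(.data$value)) |>
      dplyr::mutate(value = split_multi(.data$value)) |>
      tidyr::unnest_longer("value") |>
      dplyr::distinct(.data$species_id, .data$value)
    counted <- dplyr::count(pairs, .data$value, name = "count")
  } else if (attribute == "family") {
    counted <- ds$species |>
      dplyr::filter(!is.na(.data$family)) |>
      dplyr::count(value = .data$family, name = "count")
  } else {
    counted <- ds$informants |>
      dplyr::filter(.data$included, !is.na(.data$knowledge_sources)) |>
      dplyr::mutate(value = split_multi(.data$knowledge_sources)) |>
      tidyr::unnest_longer("value") |>
      dplyr::distinct(.data$informant_id, .data$value) |>
      dplyr::count(.data$value, name = "count")
  }
  denom <- sum(counted$count)
  out <- counted |>
    dplyr::mutate(pct = if (denom > 0) round_half_up(100 * .data$count / denom, digits)
                  else numeric(nrow(counted))) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$value)
  attr(out, "denominator") <- denom
  attr(out, "attribute") <- attribute
  out
}

#' Demographic summary of the informant panel
#'
#' Summarises who holds the medicinal-plant knowledge: frequency tables for
#' gender, age band, education, township and knowledge source (the latter
#' multi-counted per informant), the mean number of distinct species cited
#' per gender, and the female/male knowledge ratio.
#'
#' @param ds A [survey_dataset()].
#' @param digits Display rounding.
#' @return A list with elements `knowledge_by_gender` (tibble: `gender`,
#'   `n_informants`, `mean_distinct_species`), `female_male_ratio` (NA when
#'   either gender is absent or the male mean is zero), and `tables` (named
#'   list of frequency tibbles).
#' @export
demographic_summary <- function(ds, digits = 2) {
  stopifnot(inherits(ds, "survey_dataset"))
  inc <- dplyr::filter(ds$informants, .data$included)
  if (nrow(inc) == 0) stop("no included informants", call. = FALSE)

  distinct_species <- ds$reports |>
    dplyr::distinct(.data$informant_id, .data$species_id) |>
    dplyr::count(.data$informant_id, name = "k")
  by_gender <- inc |>
    dplyr::left_join(distinct_species, by = "informant_id") |>
    dplyr::mutate(k = dplyr::coalesce(.data$k, 0L)) |>
    dplyr::group_by(.data$gender) |>
    dplyr::summarise(n_informants = dplyr::n(),
                     mean_distinct_species = mean(.data$k), .groups = "drop")

  gmean <- function(g) {
    v <- by_gender$mean_distinct_species[by_gender$gender == g]
    if (length(v) == 1) v else NA_real_
  }
  ratio <- if (!is.na(gmean("female")) && !is.na(gmean("male")) && gmean("male") > 0) {
    gmean("female") / gmean("male")
  } else {
    NA_real_
  }

  simple_table <- function(col) {
    inc |>
      dplyr::filter(!is.na(.data[[col]])) |>
      dplyr::count(value = .data[[col]], name = "count") |>
      dplyr::mutate(pct = round_half_up(100 * .data$count / sum(.data$count), digits)) |>
      dplyr::arrange(dplyr::desc(.data$count), .data$value)
  }
  tables <- list(gender = simple_table("gender"),
                 age_band = simple_table("age_band"),
                 education = simple_table("education"),
                 township = simple_table("township"),
                 knowledge_source = tabulate_attribute(ds, "knowledge_source",
                                                       digits = digits))
  list(knowledge_by_gender = by_gender,
       female_male_ratio = ratio,
       tables = tables)
}
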