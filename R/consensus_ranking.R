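#' Rank plants within an ICPC category by citation frequency
#'
#' Restricting the use reports to one ailment category, counts the distinct
#' informants citing each species for that category (the category-level FC).
#' This is the final step of the consensus reading: within a high-consensus
#' category, the species with the highest category FC are the ones the
#' community actually agrees on.
#'
#' @param ds A [survey_dataset()].
#' @param category An ICPC category label (see [icpc_categories()]).
#' @param ailment_map Mapping `ailment_text` -> `icpc_category`; defaults to
#'   the dataset's map.
#' @return A tibble `species_id`, `canonical_name`, `category_fc`, ordered
#'   by `category_fc` descending, ties by `canonical_name`.
#' @export
rank_plants_in_category <- function(ds, category, ailment_map = ds$ailment_map) {
  stopifnot(inherits(ds, "survey_dataset"))
  if (is.null(ailment_map)) stop("an ailment map is required", call. = FALSE)
  if (!category %in% icpc_categories()) {
    stop(sprintf("unknown ICPC category '%s'", category), call. = FALSE)
  }
  ds$reports |>
    dplyr::inner_join(ailment_map, by = "ailment_text",
                      relationship = "many-to-one") |>
    dplyr::filter(.data$icpc_category == category) |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(category_fc = dplyr::n_distinct(.data$informant_id),
                     .groups = "drop") |>
    dplyr::left_join(dplyr::select(ds$species, "species_id", "canonical_name"),
                     by = "species_id") |>
    dplyr::select("species_id", "canonical_name", "category_fc") |>
    dplyr::arrange(dplyr::desc(.data$category_fc), .data$canonical_name)
}

#' Three-step consensus interpretation
#'
#' Implements the standard reading of the consensus table: first screen the
#' ailment categories by their Fic value (high Fic means informants agree on
#' which taxa treat the category); second inspect Nur — a large report count
#' marks the category as a common local disease; finally rank the plants
#' cited within each retained category by their category-restricted
#' frequency of citation.
#'
#' @param fic_rows Output of [compute_fic()].
#' @param ds The [survey_dataset()] the rows were computed from.
#' @param fic_threshold Categories with `fic_raw >= fic_threshold` are
#'   retained (in `[0, 1]`).
#' @param nur_threshold Categories with `nur >= nur_threshold` are flagged
#'   as common local diseases (non-negative).
#' @param ailment_map Mapping used for the category-level plant ranking.
#' @return An object of class `consensus_report`: a tibble of retained
#'   categories (fic descending, ties by nur descending) with a
#'   `flagged_common_disease` logical and a `plants` list-column of ranked
#'   `(species, category_fc)` tibbles.
#' @export
interpret_consensus <- function(fic_rows, ds, fic_threshold = 0.8,
                                nur_threshold = 50,
                                ailment_map = ds$ailment_map) {
  stopifnot(inherits(ds, "survey_dataset"))
  if (fic_threshold < 0 || fic_threshold > 1) {
    stop("fic_threshold must be in [0, 1]", call. = FALSE)
  }
  if (nur_threshold < 0) stop("nur_threshold must be >= 0", call. = FALSE)

  kept <- fic_rows |>
    dplyr::filter(.data$fic_raw >= fic_threshold) |>
    dplyr::arrange(dplyr::desc(.data$fic_raw), dplyr::desc(.data$nur),
                   .data$icpc_category) |>
    dplyr::mutate(flagged_common_disease = .data$nur >= nur_threshold)
  kept$plants <- lapply(kept$icpc_category, function(cat) {
    rank_plants_in_category(ds, cat, ailment_map = ailment_map)
  })
  structure(kept, class = c("consensus_report", class(kept)))
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf("<consensus_report> %d retained categories\n", nrow(x)))
  for (i in seq_len(nrow(x))) {
    top <- x$plants[[i]]
    lead <- if (nrow(top) > 0) {
      sprintf("top: %s (FC=%d)", top$canonical_name[1], top$category_fc[1])
    } else "no plants"
    cat(sprintf("  %-34s Fic=%.2f Nur=%-4d %s%s\n",
                x$icpc_category[i], x$fic[i], x$nur[i],
                if (x$flagged_common_disease[i]) "[common] " else "", lead))
  }
  invisible(x)
}
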