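#' Reconstruct a survey from per-species citation totals
#'
#' Published index tables report only the marginals: the total use reports
#' per species (\eqn{\Sigma U_i}) and the number of distinct citing
#' informants (FC). This helper builds a minimal long-format survey with
#' exactly those marginals — FC informants each citing the species for one
#' ailment, with the surplus `sum_ui - fc` reports assigned as second
#' ailments of the first informants — so the index computations can be
#' exercised against printed values.
#'
#' @param totals Tibble with columns `canonical_name`, `sum_ui`, `fc`, and
#'   optionally `family`.
#' @param n_informants Included-informant denominator N.
#' @param n_excluded Extra excluded respondents to emit.
#' @return A [survey_dataset()].
#' @export
survey_from_citation_totals <- function(totals, n_informants,
                                        n_excluded = 0L) {
  stopifnot(all(c("canonical_name", "sum_ui", "fc") %in% names(totals)),
            all(totals$fc <= n_informants), all(totals$sum_ui >= totals$fc),
            all(totals$sum_ui - totals$fc <= totals$fc))
  n_total <- n_informants + n_excluded
  informants <- tibble::tibble(
    informant_id = sprintf("INF%03d", seq_len(n_total)),
    gender = rep(c("female", "male"), length.out = n_total),
    age_band = ">60", township = "Jincheng", education = "elementary",
    knowledge_sources = "oral-transmission",
    included = rep(c(TRUE, FALSE), c(n_informants, n_excluded)))
  species <- tibble::tibble(
    species_id = sprintf("SP%03d", seq_len(nrow(totals))),
    canonical_name = totals$canonical_name,
    family = if ("family" %in% names(totals)) totals$family else "Unknownaceae",
    local_names = NA_character_, voucher_id = NA_character_,
    source = "wild", red_list_status = NA_character_)
  reports <- purrr::map_dfr(seq_len(nrow(totals)), function(i) {
    fc <- totals$fc[i]
    extra <- totals$sum_ui[i] - fc
    tibble::tibble(
      informant_id = sprintf("INF%03d", c(seq_len(fc), seq_len(extra))),
      species_id = sprintf("SP%03d", i),
      ailment_text = c(rep("general-unspecified-complaint-1", fc),
                       rep("general-unspecified-complaint-2", extra)),
      part = "Wp", preparation = "decoction-fresh", route = "oral")
  })
  ailment_map <- tibble::tibble(
    ailment_text = c("general-unspecified-complaint-1",
                     "general-unspecified-complaint-2"),
    icpc_category = "general-unspecified")
  survey_dataset(informants, species, reports, ailment_map = ailment_map)
}

#' Reconstruct a survey from per-category consensus counts
#'
#' Builds a survey whose mapped use reports reproduce given `(Nur, Nt)`
#' pairs per ICPC category: each category receives `nt` distinct species,
#' one report per species from distinct informants, and the surplus
#' `nur - nt` reports go to the category's first species from further
#' distinct informants. Fic computed on the result therefore equals the
#' formula value for the printed counts.
#'
#' @param counts Tibble with columns `icpc_category`, `nur`, `nt`.
#' @param n_informants Number of included informants (must cover the
#'   largest per-category report count).
#' @return A [survey_dataset()].
#' @export
survey_from_category_counts <- function(counts, n_informants = max(counts$nur)) {
  stopifnot(all(c("icpc_category", "nur", "nt") %in% names(counts)),
            all(counts$nt >= 1), all(counts$nt <= counts$nur),
            n_informants >= max(counts$nur))
  informants <- tibble::tibble(
    informant_id = sprintf("INF%03d", seq_len(n_informants)),
    gender = "female", age_band = ">60", township = "Jincheng",
    education = "elementary", knowledge_sources = "oral-transmission",
    included = TRUE)
  n_species_total <- sum(counts$nt)
  species <- tibble::tibble(
    species_id = sprintf("SP%03d", seq_len(n_species_total)),
    canonical_name = paste("Genus", sprintf("species%03d", seq_len(n_species_total))),
    family = "Unknownaceae", local_names = NA_character_,
    voucher_id = NA_character_, source = "wild",
    red_list_status = NA_character_)
  offset <- c(0L, cumsum(counts$nt))
  reports <- purrr::map_dfr(seq_len(nrow(counts)), function(i) {
    nt <- counts$nt[i]; nur <- counts$nur[i]
    sp <- sprintf("SP%03d", offset[i] + seq_len(nt))
    # one report per taxon, surplus reports pile onto the first taxon,
    # each from a distinct informant so records stay unique triples
    species_seq <- c(sp, rep(sp[1], nur - nt))
    tibble::tibble(
      informant_id = sprintf("INF%03d", seq_len(nur)),
      species_id = species_seq,
      ailment_text = paste0(counts$icpc_category[i], "-complaint-1"),
      part = "Wp", preparation = "decoction-fresh", route = "oral")
  })
  ailment_map <- tibble::tibble(
    ailment_text = paste0(counts$icpc_category, "-complaint-1"),
    icpc_category = counts$icpc_category)
  survey_dataset(informants, species, reports, ailment_map = ailment_map)
}
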