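#' Construct a reference flora
#'
#' A reference flora models one published catalogue a survey is compared
#' against: a regional flora, a materia medica record, or a membership-only
#' regulatory list (food raw materials, herbal pharmacopeia). It carries the
#' canonicalized species set and, optionally, a species -> use-term map in a
#' controlled vocabulary shared with the survey's ailment mapping.
#'
#' @param name Label for the reference work.
#' @param species Character vector of species names (canonicalized on
#'   construction).
#' @param uses Optional named list: canonical species name -> character
#'   vector of use terms. Names must be a subset of `species`.
#' @return An object of class `reference_flora`.
#' @export
reference_flora <- function(name, species, uses = NULL) {
  species <- unique(canonicalize_name(species))
  if (!is.null(uses)) {
    names(uses) <- canonicalize_name(names(uses))
    extra <- setdiff(names(uses), species)
    if (length(extra) > 0) {
      stop(sprintf("use map names species absent from the reference: %s",
                   paste(utils::head(extra, 3), collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(name = name, species = species, uses = uses),
            class = "reference_flora")
}

#' @export
print.reference_flora <- function(x, ...) {
  cat(sprintf("<reference_flora> '%s': %d species%s\n", x$name,
              length(x$species),
              if (is.null(x$uses)) "" else sprintf(", uses for %d", length(x$uses))))
  invisible(x)
}

#' Species-set overlap with a reference flora
#'
#' Counts how many survey species appear in the reference and reports the
#' percentage over the survey species count (half-up rounding). This is the
#' membership comparison used to quantify how much of a local pharmacopoeia
#' is already documented in neighbouring literature.
#'
#' @param survey_species Character vector of canonical survey species names.
#' @param ref A [reference_flora()].
#' @param digits Display rounding for the percentage.
#' @return A tibble row: `reference`, `n_survey`, `n_matched`, `pct`.
#' @export
flora_overlap <- function(survey_species, ref, digits = 2) {
  stopifnot(inherits(ref, "reference_flora"))
  survey_species <- unique(survey_species)
  if (length(survey_species) == 0) {
    stop("empty survey species set", call. = FALSE)
  }
  n_matched <- sum(survey_species %in% ref$species)
  tibble::tibble(reference = ref$name,
                 n_survey = length(survey_species),
                 n_matched = n_matched,
                 pct = round_half_up(100 * n_matched / length(survey_species), digits))
}

survey_use_sets <- function(ds, use_map) {
  uses <- ds$reports |>
    dplyr::inner_join(use_map, by = "ailment_text",
                      relationship = "many-to-one") |>
    dplyr::left_join(dplyr::select(ds$species, "species_id", "canonical_name"),
                     by = "species_id") |>
    dplyr::distinct(.data$canonical_name, use = .data[[setdiff(names(use_map), "ailment_text")[1]]])
  split(uses$use, uses$canonical_name)
}

#' Shared-use agreement across references
#'
#' Counts the survey species whose recorded uses agree with *every* listed
#' reference: a species is shared when, in each reference's use map, its use
#' set intersects the species' survey use set (both expressed in the same
#' controlled vocabulary, into which the survey's free-text ailments are
#' mapped by `use_map`). The percentage is over all survey species.
#'
#' @param ds A [survey_dataset()].
#' @param refs List of [reference_flora()] objects, each with a use map.
#' @param use_map Tibble mapping `ailment_text` to a use-term column (an
#'   ICPC ailment map works directly).
#' @param digits Display rounding.
#' @return A list: `n_shared`, `pct`, and `shared_species` (character).
#' @export
shared_use <- function(ds, refs, use_map = ds$ailment_map, digits = 2) {
  stopifnot(inherits(ds, "survey_dataset"))
  if (is.null(use_map)) stop("a use map is required", call. = FALSE)
  for (ref in refs) {
    stopifnot(inherits(ref, "reference_flora"))
    if (is.null(ref$uses)) {
      stop(sprintf("reference '%s' has no use map", ref$name), call. = FALSE)
    }
  }
  survey_uses <- survey_use_sets(ds, use_map)
  n_survey <- dplyr::n_distinct(ds$species$canonical_name)
  shared <- names(survey_uses)[vapply(names(survey_uses), function(sp) {
    all(vapply(refs, function(ref) {
      ref_uses <- ref$uses[[sp]]
      !is.null(ref_uses) && length(intersect(survey_uses[[sp]], ref_uses)) > 0
    }, logical(1)))
  }, logical(1))]
  list(n_shared = length(shared),
       pct = round_half_up(100 * length(shared) / n_survey, digits),
       shared_species = sort(shared))
}

#' Detect novel species and novel uses
#'
#' Splits the survey against a set of references: `novel_species` are the
#' survey species absent from every reference's species list; `novel_uses`
#' are the survey (species, use) pairs recorded in no reference use map.
#' Uses belonging to novel species are kept in the novel-use table but
#' flagged (`is_novel_species`), mirroring the convention of reporting new
#' medicine types separately from new uses of known plants.
#'
#' @param ds A [survey_dataset()].
#' @param refs List of [reference_flora()] objects. References without a use
#'   map contribute to species membership only.
#' @param use_map Mapping `ailment_text` -> use term; defaults to the
#'   dataset's ailment map.
#' @return A list: `novel_species` (character), `novel_uses` (tibble
#'   `canonical_name`, `use`, `is_novel_species`), `n_novel_species`,
#'   `n_novel_uses`.
#' @export
detect_novelty <- function(ds, refs, use_map = ds$ailment_map) {
  stopifnot(inherits(ds, "survey_dataset"))
  survey_species <- unique(ds$species$canonical_name)
  ref_species <- unique(unlist(lapply(refs, function(r) r$species)))
  novel_species <- sort(setdiff(survey_species, ref_species))

  novel_uses <- tibble::tibble(canonical_name = character(), use = character(),
                               is_novel_species = logical())
  if (!is.null(use_map) && nrow(ds$reports) > 0) {
    survey_uses <- survey_use_sets(ds, use_map)
    refs_with_uses <- Filter(function(r) !is.null(r$uses), refs)
    pairs <- tibble::tibble(
      canonical_name = rep(names(survey_uses), lengths(survey_uses)),
      use = unlist(survey_uses, use.names = FALSE))
    known <- vapply(seq_len(nrow(pairs)), function(i) {
      any(vapply(refs_with_uses, function(ref) {
        pairs$use[i] %in% ref$uses[[pairs$canonical_name[i]]]
      }, logical(1)))
    }, logical(1))
    novel_uses <- pairs[!known, , drop = FALSE] |>
      dplyr::mutate(is_novel_species = .data$canonical_name %in% novel_species) |>
      dplyr::arrange(.data$canonical_name, .data$use)
  }
  list(novel_species = novel_species,
       novel_uses = novel_uses,
       n_novel_species = length(novel_species),
       n_novel_uses = nrow(novel_uses))
}

#' Tally species by an annotation field
#'
#' Counts species per value of an annotation column of the species table —
#' typically `red_list_status` for conservation tallies. Species lacking the
#' annotation are counted under an explicit `"unannotated"` bucket so the
#' counts always sum to the number of species.
#'
#' @param ds A [survey_dataset()].
#' @param annotation_field Column of the species table; default
#'   `"red_list_status"`.
#' @param digits Display rounding.
#' @return A tibble `value`, `count`, `pct` with attribute `"denominator"`.
#' @export
annotation_counts <- function(ds, annotation_field = "red_list_status",
                              digits = 2) {
  stopifnot(inherits(ds, "survey_dataset"))
  if (!annotation_field %in% names(ds$species)) {
    stop(sprintf("unknown annotation field '%s'", annotation_field), call. = FALSE)
  }
  vals <- ds$species[[annotation_field]]
  vals[is.na(vals) | !nzchar(trimws(as.character(vals)))] <- "unannotated"
  out <- tibble::tibble(value = as.character(vals)) |>
    dplyr::count(.data$value, name = "count") |>
    dplyr::mutate(pct = round_half_up(100 * .data$count / sum(.data$count), digits)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$value)
  attr(out, "denominator") <- nrow(ds$species)
  out
}
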