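#' Build informant baskets
#'
#' Turns the long-format report table into itemset-mining input: one basket
#' per included informant holding the deduplicated set of species that
#' informant cited (for any ailment). Informants with no reports keep an
#' empty basket, so the basket count always equals N.
#'
#' @param ds A [survey_dataset()].
#' @return A tibble `informant_id`, `species` (list-column of character
#'   vectors of species ids).
#' @export
build_baskets <- function(ds) {
  stopifnot(inherits(ds, "survey_dataset"))
  inc <- ds$informants$informant_id[ds$informants$included]
  pairs <- dplyr::distinct(ds$reports, .data$informant_id, .data$species_id)
  sets <- split(pairs$species_id, pairs$informant_id)
  tibble::tibble(
    informant_id = inc,
    species = lapply(inc, function(i) sort(unname(sets[[i]] %||% character(0)))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

basket_incidence <- function(baskets) {
  species <- sort(unique(unlist(baskets$species)))
  m <- matrix(0L, nrow = nrow(baskets), ncol = length(species),
              dimnames = list(baskets$informant_id, species))
  for (i in seq_len(nrow(baskets))) {
    m[i, baskets$species[[i]]] <- 1L
  }
  m
}

#' Mine pairwise co-use association rules
#'
#' For every ordered species pair (A, B) computes the association-rule
#' statistics over informant baskets: `support_count` — the number of
#' informants citing both species; `support_frac` — that count over the
#' number of baskets N; and `confidence` — the conditional probability of B
#' being cited given that A is, `support_count / count(A)`. Rules meeting
#' both thresholds are returned in a deterministic order (support
#' descending, then antecedent, then consequent), making the output directly
#' comparable across runs.
#'
#' Only pairs are mined: the co-use network of an ethnobotanical survey is
#' pairwise, and higher-order itemsets add nothing to it.
#'
#' @param baskets Output of [build_baskets()].
#' @param min_support Minimum number of co-citing informants (>= 1).
#' @param min_confidence Minimum confidence in `[0, 1]`.
#' @return A tibble `antecedent`, `consequent`, `support_count`,
#'   `support_frac`, `confidence`.
#' @export
mine_rules <- function(baskets, min_support = 2, min_confidence = 0.5) {
  stopifnot(min_support >= 1, min_confidence >= 0, min_confidence <= 1)
  n <- nrow(baskets)
  empty <- tibble::tibble(antecedent = character(), consequent = character(),
                          support_count = integer(), support_frac = numeric(),
                          confidence = numeric())
  if (n == 0) return(empty)
  m <- basket_incidence(baskets)
  if (ncol(m) < 2) return(empty)
  co <- crossprod(m)                     # co[i, j] = informants citing both
  item_count <- diag(co)
  species <- colnames(m)
  idx <- which(upper.tri(co) & co >= min_support, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  both <- rbind(idx, idx[, c(2, 1), drop = FALSE])   # both rule directions
  rules <- tibble::tibble(
    antecedent = species[both[, 1]],
    consequent = species[both[, 2]],
    support_count = as.integer(co[both]),
    support_frac = as.integer(co[both]) / n,
    confidence = as.integer(co[both]) / unname(item_count[both[, 1]]))
  rules |>
    dplyr::filter(.data$confidence >= min_confidence) |>
    dplyr::arrange(dplyr::desc(.data$support_count), .data$antecedent,
                   .data$consequent)
}

#' Assemble the co-use network
#'
#' Collapses the directed rule list into an undirected species co-use graph:
#' one edge per unordered pair with the pair's support count, annotated with
#' the confidence in each direction, and one node per species in
#' `index_rows` weighted by its global frequency of citation. Species with
#' no qualifying pair appear as isolated nodes.
#'
#' @param rules Output of [mine_rules()].
#' @param index_rows Output of [compute_species_indices()] on the same
#'   dataset (supplies the node set and fc weights).
#' @return An undirected `igraph` graph with vertex attribute `fc` and edge
#'   attributes `support_count`, `confidence_fwd` (from the
#'   alphabetically-first endpoint), `confidence_rev`.
#' @export
to_network <- function(rules, index_rows) {
  missing_sp <- setdiff(unique(c(rules$antecedent, rules$consequent)),
                        index_rows$species_id)
  if (length(missing_sp) > 0) {
    stop(sprintf("rule species absent from index rows: %s",
                 paste(utils::head(missing_sp, 3), collapse = ", ")), call. = FALSE)
  }
  edges <- rules |>
    dplyr::mutate(a = pmin(.data$antecedent, .data$consequent),
                  b = pmax(.data$antecedent, .data$consequent),
                  fwd = .data$antecedent <= .data$consequent) |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(
      support_count = .data$support_count[1],
      confidence_fwd = dplyr::first(.data$confidence[.data$fwd], default = NA_real_),
      confidence_rev = dplyr::first(.data$confidence[!.data$fwd], default = NA_real_),
      .groups = "drop") |>
    dplyr::arrange(.data$a, .data$b)
  vertices <- tibble::tibble(name = index_rows$species_id, fc = index_rows$fc)
  igraph::graph_from_data_frame(
    dplyr::rename(edges, from = "a", to = "b"),
    directed = FALSE, vertices = vertices)
}

#' Export / import a co-use network
#'
#' Writes the network either as standard GraphML or as a flat edge-list CSV
#' (with a companion `<path>.nodes.csv` holding the isolated-node weights),
#' both chosen so that `import_network()` restores an isomorphic graph with
#' identical attributes.
#'
#' @param net An `igraph` graph from [to_network()].
#' @param path Output file path.
#' @param format `"graphml"` or `"edge-csv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "edge-csv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    edges <- igraph::as_data_frame(net, what = "edges")
    nodes <- igraph::as_data_frame(net, what = "vertices")
    readr::write_csv(tibble::as_tibble(edges), path, na = "", progress = FALSE)
    readr::write_csv(tibble::as_tibble(nodes), paste0(path, ".nodes.csv"),
                     na = "", progress = FALSE)
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("graphml", "edge-csv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else {
    edges <- readr::read_csv(path, show_col_types = FALSE, na = "", progress = FALSE)
    nodes <- readr::read_csv(paste0(path, ".nodes.csv"), show_col_types = FALSE,
                             na = "", progress = FALSE)
    igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  }
}
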