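#' Run the full survey analysis pipeline
#'
#' Orchestrates validate -> indices -> consensus -> crossref -> network over
#' one survey and writes every stage's output plus a run manifest and a
#' markdown summary to `out_dir`. Each stage is a pure function of the
#' loaded inputs, so rerunning with the same inputs and configuration
#' reproduces every output except the manifest timestamps.
#'
#' Outputs: `indices.csv`, `fic.csv`, `freq_<attribute>.csv`,
#' `consensus_report.json`, `crossref.csv` and `novelty.csv` (when
#' references are given), `network.graphml`, `summary.md`, `manifest.json`.
#'
#' @param input A survey directory (see [load_survey()]) or a
#'   `survey_dataset`.
#' @param out_dir Output directory, created if needed.
#' @param config An [analysis_config()].
#' @param refs Optional list of [reference_flora()] objects for the
#'   cross-reference stage.
#' @param fic_threshold,nur_threshold Consensus screening thresholds (see
#'   [interpret_consensus()]).
#' @return `out_dir`, invisibly. Stage failures abort with the stage name.
#' @export
run_all <- function(input, out_dir, config = analysis_config(), refs = NULL,
                    fic_threshold = 0.8, nur_threshold = 50) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  digits <- config$rounding_digits

  ds <- stage("load", {
    if (inherits(input, "survey_dataset")) input else load_survey(input, config)
  })
  issues <- stage("validate", validate_survey(ds))
  if (any(issues$severity == "error")) {
    stop(sprintf("pipeline stage 'validate' failed: %d structural issue(s), first: %s",
                 sum(issues$severity == "error"),
                 issues$message[issues$severity == "error"][1]), call. = FALSE)
  }

  idx <- stage("indices", compute_species_indices(ds, digits = digits))
  fic <- stage("indices", compute_fic(
    ds, fic_degenerate_value = config$fic_degenerate_value, digits = digits))
  freq <- stage("indices", {
    lapply(stats::setNames(nm = c("part", "preparation", "route", "family")),
           function(a) tabulate_attribute(ds, a, digits = digits))
  })
  readr::write_csv(idx, file.path(out_dir, "indices.csv"), na = "", progress = FALSE)
  readr::write_csv(fic, file.path(out_dir, "fic.csv"), na = "", progress = FALSE)
  for (a in names(freq)) {
    readr::write_csv(freq[[a]], file.path(out_dir, sprintf("freq_%s.csv", a)),
                     na = "", progress = FALSE)
  }

  consensus <- stage("consensus", interpret_consensus(
    fic, ds, fic_threshold = fic_threshold, nur_threshold = nur_threshold))
  consensus_json <- lapply(seq_len(nrow(consensus)), function(i) {
    list(icpc_category = consensus$icpc_category[i],
         fic = consensus$fic[i], nur = consensus$nur[i], nt = consensus$nt[i],
         flagged_common_disease = consensus$flagged_common_disease[i],
         plants = consensus$plants[[i]])
  })
  jsonlite::write_json(consensus_json,
                       file.path(out_dir, "consensus_report.json"),
                       auto_unbox = TRUE, digits = NA)

  if (!is.null(refs)) {
    crossref <- stage("crossref", {
      dplyr::bind_rows(lapply(refs, function(r) {
        flora_overlap(ds$species$canonical_name, r, digits = digits)
      }))
    })
    novelty <- stage("crossref", detect_novelty(ds, refs))
    readr::write_csv(crossref, file.path(out_dir, "crossref.csv"), na = "",
                     progress = FALSE)
    readr::write_csv(novelty$novel_uses, file.path(out_dir, "novelty.csv"),
                     na = "", progress = FALSE)
  } else {
    crossref <- NULL
  }

  net <- stage("network", {
    rules <- mine_rules(build_baskets(ds), min_support = config$min_support,
                        min_confidence = config$min_confidence)
    to_network(rules, idx)
  })
  stage("network", export_network(net, file.path(out_dir, "network.graphml"),
                                  format = "graphml"))

  stage("summary", write_summary_md(file.path(out_dir, "summary.md"),
                                    ds, idx, fic, crossref, net))
  stage("manifest", write_manifest(file.path(out_dir, "manifest.json"),
                                   input, out_dir, config))
  invisible(out_dir)
}

write_summary_md <- function(path, ds, idx, fic, crossref, net) {
  fmt_tbl <- function(df) {
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                          ~ format(.x, digits = 6)))
    header <- paste(names(df), collapse = " | ")
    sep <- paste(rep("---", ncol(df)), collapse = " | ")
    rows <- apply(df, 1, paste, collapse = " | ")
    paste(c(header, sep, rows), collapse = "\n")
  }
  lines <- c(
    "# Survey analysis summary", "",
    sprintf("Informants (included): %d; species: %d; use reports: %d.",
            ds$n_informants, nrow(ds$species), nrow(ds$reports)), "",
    "## Species indices (top 10 by UV)", "",
    fmt_tbl(utils::head(dplyr::select(idx, "canonical_name", "sum_ui", "uv",
                                      "fc", "rfc"), 10)), "",
    "## Informant consensus by ICPC category", "",
    fmt_tbl(dplyr::select(fic, "icpc_category", "nur", "nt", "fic")), "")
  if (!is.null(crossref)) {
    lines <- c(lines, "## Literature cross-reference", "", fmt_tbl(crossref), "")
  }
  lines <- c(lines,
             sprintf("Co-use network: %d nodes, %d edges.",
                     igraph::vcount(net), igraph::ecount(net)))
  writeLines(lines, path)
  invisible(path)
}

write_manifest <- function(path, input, out_dir, config) {
  input_digests <- if (is.character(input) && dir.exists(input)) {
    files <- list.files(input, pattern = "\\.csv$", full.names = TRUE)
    as.list(stats::setNames(unname(tools::md5sum(files)), basename(files)))
  } else {
    list(note = "in-memory survey_dataset input")
  }
  outputs <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    tool = "ethnoconsensus",
    version = as.character(utils::packageVersion("ethnoconsensus")),
    seed = config$seed,
    config = unclass(config),
    input_digests = input_digests,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
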