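#' Controlled vocabularies for use-report attributes
#'
#' The survey schema constrains plant part, preparation method, and
#' administration route to fixed token sets, and ailments are grouped into the
#' twelve ICPC (International Classification of Primary Care) chapters that
#' occur in medicinal-plant surveys of this kind. These accessors return the
#' canonical token vectors; `validate_survey()` checks report fields against
#' them.
#'
#' Part tokens follow the herbarium shorthand: Le leaves, St stems, Ro roots,
#' Fr fruits, Wp whole plant, Se seeds, Fl flowers, Cx calyx.
#'
#' @return A character vector of allowed tokens.
#' @export
part_vocabulary <- function() {
  c("Le", "St", "Ro", "Fr", "Wp", "Se", "Fl", "Cx")
}

#' @rdname part_vocabulary
#' @export
preparation_vocabulary <- function() {
  c("decoction-fresh", "decoction-dried", "crush", "soak", "raw",
    "fry", "juice", "burn", "cook-with-meat", "honey-maceration")
}

#' @rdname part_vocabulary
#' @export
route_vocabulary <- function() {
  c("oral", "apply-to-injuries", "apply-to-skin", "fomentation",
    "chew", "bath", "fumigation", "fill-teeth")
}

#' @rdname part_vocabulary
#' @export
icpc_categories <- function() {
  c("musculoskeletal",
    "eye",
    "respiratory",
    "blood-blood-forming-lymph-spleen",
    "general-unspecified",
    "digestive",
    "urological",
    "female-genital-breast",
    "endocrine-metabolic-nutritional",
    "psychological",
    "cardiovascular",
    "male-genital")
}

#' @rdname part_vocabulary
#' @export
red_list_vocabulary <- function() {
  c("EN", "VU", "NT", "LC", "DD", "NA")
}

# inner separator for multi-valued CSV cells ("Le;Ro")
MULTI_SEP <- ";"

split_multi <- function(x) {
  strsplit(as.character(x), MULTI_SEP, fixed = TRUE)
}
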