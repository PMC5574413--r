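# Cached access to the packaged keyword lexicon and the category constants
# derived from it.

the <- new.env(parent = emptyenv())

caro_lexicon <- function() {
  if (is.null(the$lexicon)) {
    path <- system.file("extdata", "lexicon.yaml", package = "carofp")
    the$lexicon <- yaml::read_yaml(path)
  }
  the$lexicon
}

#' The 23 chemical modification categories
#'
#' Every element of a positional carotenoid fingerprint belongs to exactly one
#' of 23 chemical modification patterns (hydroxylation, saturation,
#' cyclization of end groups, ketolation, desaturation, ...). The vector is
#' ordered by descending occurrence in the curated carotenoid corpus.
#'
#' @return A character vector of length 23.
#' @examples
#' modification_categories()
#' @export
modification_categories <- function() {
  as.character(caro_lexicon()$categories)
}

end_group_names <- function() as.character(caro_lexicon()$end_groups)

mult_prefixes <- function() unlist(caro_lexicon()$multiplicative)

# token -> category for single-locant substituent/suffix tokens
token_category_map <- function() {
  if (is.null(the$token_cat)) {
    lex <- caro_lexicon()
    subs <- vapply(lex$substituents, function(x) c(x$token, x$category), character(2))
    sufs <- vapply(lex$suffixes, function(x) c(x$token, x$category), character(2))
    skel <- vapply(lex$skeletal, function(x) c(x$token, x$category), character(2))
    m <- cbind(subs, sufs, skel)
    the$token_cat <- setNames(m[2, ], m[1, ])
  }
  the$token_cat
}

bridge_category_map <- function() {
  if (is.null(the$bridge_cat)) {
    lex <- caro_lexicon()
    the$bridge_cat <- vapply(lex$bridges, function(x) x$category, character(1)) |>
      setNames(vapply(lex$bridges, function(x) x$token, character(1)))
  }
  the$bridge_cat
}

# Canonical rendering order of categories within a fingerprint string.
# Reverse-engineered so that the canonical renderer reproduces the printed
# element order of all reference fingerprints; a dialect choice of this
# package (see the methods vignette).
render_category_order <- function() {
  c("stereoisomer-RS", "cis-trans-isomerization", "desaturation", "saturation",
    "hydroxylation", "alkoxylation", "esterification", "glycosidation",
    "aldehyde-addition", "carbonylation", "ketolation", "sulfation",
    "epoxidation", "nor", "seco", "retro", "olide", "apo",
    "isoprene-polymerization", "geranylgeranyl-polymerization",
    "complex-polymerization", "cycloaddition", "cyclization-of-end-groups")
}
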