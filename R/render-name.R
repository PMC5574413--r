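# Inverse of parse_name: renders a canonical ASCII semi-systematic name.
# Canonical dialect: detachable prefixes alphabetically, then dehydro, then
# hydro (nondetachable hydrogenation, as in the nomenclature), then apo/stem,
# then suffixes. The final "e" of "carotene" is elided before a suffix.

mult_word <- function(n) {
  words <- c("", "di", "tri", "tetra", "penta", "hexa", "hepta", "octa")
  if (n < 1L || n > 8L) {
    abort_caro("locant_count_mismatch",
               sprintf("No multiplicative prefix for count %d", n))
  }
  words[n]
}

token_to_prefix_keyword <- function() {
  lex <- caro_lexicon()
  toks <- vapply(lex$substituents, function(x) x$token, character(1))
  # first lexicon spelling wins for tokens with synonyms (Ethanoyloxy)
  setNames(names(toks), toks)[!duplicated(toks)]
}

token_to_suffix_keyword <- function() {
  lex <- caro_lexicon()
  toks <- vapply(lex$suffixes, function(x) x$token, character(1))
  setNames(names(toks), toks)
}

render_locant_run <- function(pos, primed) {
  o <- locant_order(pos, primed)
  paste(render_locant(pos[o], primed[o]), collapse = ",")
}

render_pair_run <- function(pairs) {
  o <- order(pairs$primed1, pairs$pos1, pairs$primed2, pairs$pos2)
  pairs <- pairs[o, , drop = FALSE]
  paste(unlist(Map(function(a, ap, b, bp) c(render_locant(a, ap), render_locant(b, bp)),
                   pairs$pos1, pairs$primed1, pairs$pos2, pairs$primed2)),
        collapse = ",")
}

#' Render a parsed carotenoid name back to a string
#'
#' Produces the canonical ASCII spelling of a parse; `parse_name(render_name(p))`
#' reproduces `p` for any valid parse, which is the property the synthetic
#' round-trip suite exercises.
#'
#' @param p A `caro_parsed_name` from [parse_name()].
#' @return A single name string.
#' @examples
#' render_name(parse_name("(3R)-beta,beta-caroten-3-ol"))
#' @export
render_name <- function(p) {
  stopifnot(inherits(p, "caro_parsed_name"))
  pieces <- character()

  if (nrow(p$stereo) > 0) {
    o <- locant_order(p$stereo$pos, p$stereo$primed)
    s <- p$stereo[o, , drop = FALSE]
    pieces <- c(pieces, paste0("(", paste0(render_locant(s$pos, s$primed),
                                           s$descriptor, collapse = ","), ")"))
  }

  # detachable prefixes, alphabetical by keyword
  prefix_kw <- token_to_prefix_keyword()
  frags <- setNames(character(), character())
  subs <- p$substituents
  if (nrow(subs) > 0) {
    for (tok in unique(subs$keyword)) {
      rows <- subs[subs$keyword == tok, , drop = FALSE]
      kw <- prefix_kw[[tok]]
      frags <- c(frags, setNames(
        paste0(render_locant_run(rows$pos, rows$primed), "-",
               mult_word(nrow(rows)), kw), kw))
    }
  }
  skel <- p$skeletal_ops
  nor <- skel[skel$keyword == "nor", , drop = FALSE]
  if (nrow(nor) > 0) {
    frags <- c(frags, setNames(
      paste0(render_locant_run(nor$pos, nor$primed), "-", mult_word(nrow(nor)), "nor"),
      "nor"))
  }
  br <- p$bridges
  for (kind in setdiff(unique(br$kind), "olide")) {
    rows <- br[br$kind == kind, , drop = FALSE]
    frags <- c(frags, setNames(
      paste0(render_pair_run(rows), "-", mult_word(nrow(rows)), kind), kind))
  }
  frags <- frags[order(names(frags))]
  pieces <- c(pieces, unname(frags))

  if (nrow(p$dehydro_pairs) > 0) {
    pieces <- c(pieces, paste0(render_pair_run(p$dehydro_pairs), "-",
                               mult_word(2L * nrow(p$dehydro_pairs)), "dehydro"))
  }
  if (nrow(p$hydro_pairs) > 0) {
    pieces <- c(pieces, paste0(render_pair_run(p$hydro_pairs), "-",
                               mult_word(2L * nrow(p$hydro_pairs)), "hydro"))
  }

  # stem (with apo attachment) and end groups
  apo <- skel[skel$keyword == "apo", , drop = FALSE]
  ends <- p$end_groups
  stem <- if (nrow(apo) >= 2L) {
    paste0(render_locant_run(apo$pos, apo$primed), "-diapocaroten")
  } else if (nrow(apo) == 1L) {
    lead <- if (length(ends) && ends[1] != "-") paste0(ends[1], "-") else ""
    paste0(render_locant(apo$pos, apo$primed), "-apo-", lead, "caroten")
  } else if (length(ends) == 2L && ends[2] != "-") {
    paste0(ends[1], ",", ends[2], "-caroten")
  } else if (length(ends) >= 1L && ends[1] != "-") {
    paste0(ends[1], "-caroten")
  } else {
    "caroten"
  }
  pieces <- c(pieces, stem)

  # suffixes: principal groups, then olide bridges
  sufs <- character()
  suffix_kw <- token_to_suffix_keyword()
  sfx <- p$suffix_groups
  if (nrow(sfx) > 0) {
    for (tok in unique(sfx$keyword)) {
      rows <- sfx[sfx$keyword == tok, , drop = FALSE]
      sufs <- c(sufs, paste0(render_locant_run(rows$pos, rows$primed), "-",
                             mult_word(nrow(rows)), suffix_kw[[tok]]))
    }
  }
  olide <- br[br$kind == "olide", , drop = FALSE]
  if (nrow(olide) > 0) {
    sufs <- c(sufs, paste0(render_pair_run(olide), "-", mult_word(nrow(olide)), "olide"))
  }

  body <- paste(pieces, collapse = "-")
  if (length(sufs)) paste(c(body, sufs), collapse = "-") else paste0(body, "e")
}
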