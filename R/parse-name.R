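# Parser for IUPAC semi-systematic carotenoid names. The grammar, per the
# Nomenclature of Carotenoids: an optional parenthesized stereo prefix, a
# sequence of locanted modification prefixes, a stem of two Greek end-group
# descriptors + "caroten", and optional principal-group suffixes:
#   (3R)-beta,beta-caroten-3-ol
#   (3S,...)-5,6-epoxy-3'-ethanoyloxy-3,5'-dihydroxy-6',7'-didehydro-
#       5,6,7,8,5',6'-hexahydro-beta,beta-caroten-8-one
# Apocarotenoids drop one end group ("8'-apo-beta-caroten-8'-al") or both
# ("8,8'-diapocarotene-8,8'-dial").

stem_regex <- function() {
  eg <- paste(end_group_names(), collapse = "|")
  sprintf("(?:(%s),(%s)-)?(?:(%s)-)?((?:di)?apo)?caroten", eg, eg, eg)
}

empty_stereo <- function() tibble(pos = integer(), primed = logical(),
                                  descriptor = character())
empty_pairs <- function() tibble(pos1 = integer(), primed1 = logical(),
                                 pos2 = integer(), primed2 = logical())
empty_subs <- function() tibble(pos = integer(), primed = logical(),
                                keyword = character())
empty_bridges <- function() tibble(pos1 = integer(), primed1 = logical(),
                                   pos2 = integer(), primed2 = logical(),
                                   kind = character())

new_parsed_name <- function(stereo, dehydro, hydro, substituents, bridges,
                            skeletal, suffix, end_groups, raw_name) {
  structure(
    list(stereo = stereo, dehydro_pairs = dehydro, hydro_pairs = hydro,
         substituents = substituents, bridges = bridges,
         skeletal_ops = skeletal, suffix_groups = suffix,
         end_groups = end_groups, raw_name = raw_name),
    class = "caro_parsed_name"
  )
}

#' @export
print.caro_parsed_name <- function(x, ...) {
  cat("<carotenoid name parse>\n")
  cat("  raw:        ", x$raw_name, "\n")
  cat("  end groups: ",
      if (length(x$end_groups)) paste(x$end_groups, collapse = ",") else "(none)", "\n")
  counts <- c(stereo = nrow(x$stereo), dehydro = nrow(x$dehydro_pairs),
              hydro = nrow(x$hydro_pairs), substituents = nrow(x$substituents),
              bridges = nrow(x$bridges), skeletal = nrow(x$skeletal_ops),
              suffix = nrow(x$suffix_groups))
  counts <- counts[counts > 0]
  if (length(counts))
    cat("  features:   ", paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

parse_stereo_items <- function(txt) {
  items <- str_split(txt, ",")[[1]]
  items <- str_trim(items)
  items <- items[nzchar(items)]
  out <- lapply(items, function(it) {
    m <- str_match(it, "(?i)^([0-9]+)('?)([RSZE])$")
    if (is.na(m[1, 1])) stop_unknown_keyword(it)
    pos <- as.integer(m[1, 2])
    if (pos < 1L || pos > 20L) stop_invalid_locant(it)
    tibble(pos = pos, primed = m[1, 3] == "'", descriptor = toupper(m[1, 4]))
  })
  if (!length(out)) return(empty_stereo())
  bind_rows(out)
}

#' Split a normalized carotenoid name into raw tokens
#'
#' Splits at hyphens that introduce a locant list, keeping each locant list
#' attached to its keyword, and detaches the end-group stem. A name with no
#' recognizable stem is an error.
#'
#' @param name A normalized name string (see [normalize_name()]).
#' @return Character vector of tokens, e.g.
#'   `c("(3R)", "beta,beta-caroten", "3-ol")`.
#' @examples
#' split_tokens(normalize_name("(3R)-beta,beta-caroten-3-ol"))
#' @export
split_tokens <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  parts <- decompose_name(name)
  toks <- character()
  if (nzchar(parts$stereo)) toks <- c(toks, parts$stereo)
  if (nzchar(parts$pre)) {
    toks <- c(toks, str_split(parts$pre, "-(?=[0-9(])")[[1]])
  }
  toks <- c(toks, parts$stem)
  if (nzchar(parts$post)) {
    toks <- c(toks, str_split(parts$post, "-(?=[0-9(])")[[1]])
  }
  toks[nzchar(toks)]
}

# Splits a normalized name into stereo prefix, prefix run, stem, suffix run.
decompose_name <- function(name) {
  rest <- name
  stereo <- ""
  m <- str_match(rest, "^(\\([^)]*\\))-")
  if (!is.na(m[1, 1])) {
    stereo <- m[1, 2]
    rest <- substring(rest, nchar(m[1, 1]) + 1L)
  }
  loc <- regexpr(stem_regex(), rest, perl = TRUE)
  if (loc[1] == -1L) {
    abort_caro("unparsable_name",
               sprintf("No carotenoid stem found in '%s'", name), token = name)
  }
  len <- attr(loc, "match.length")
  pre <- substring(rest, 1L, loc[1] - 1L)
  stem <- substring(rest, loc[1], loc[1] + len - 1L)
  post <- substring(rest, loc[1] + len)
  # fused diapo/apo stems pull their locants from the tail of the prefix run
  gm <- str_match(stem, paste0("^", stem_regex(), "$"))
  if (!is.na(gm[1, 5])) {
    tail_m <- str_match(pre, "([0-9',]+)-?$")
    if (!is.na(tail_m[1, 1])) {
      stem <- paste0(tail_m[1, 2], "-", stem)
      pre <- substring(pre, 1L, nchar(pre) - nchar(tail_m[1, 1]))
    }
  }
  pre <- sub("-$", "", pre)
  post <- sub("^e", "", post)
  post <- sub("^-", "", post)
  if (grepl("^[a-z]", post)) {
    abort_caro("unparsable_name",
               sprintf("Trailing text '%s' after stem in '%s'", post, name),
               token = post)
  }
  list(stereo = stereo, pre = pre, stem = stem, post = post)
}

#' Parse an IUPAC semi-systematic carotenoid name
#'
#' Produces a structured parse: stereo descriptors, dehydro/hydro bond pairs,
#' locanted substituents, bridges (epoxy/seco/retro/olide), skeletal
#' operations (apo/nor), principal-group suffixes and the Greek end-group
#' pair. The parse is loss-complete: [render_name()] reproduces an equivalent
#' name. Unknown keywords raise a classed error naming the offending token.
#'
#' @param raw The name, in any typographic dialect accepted by
#'   [normalize_name()].
#' @return A `caro_parsed_name` object.
#' @examples
#' p <- parse_name("(3R)-beta,beta-caroten-3-ol")
#' p$substituents
#' p$end_groups
#' @export
parse_name <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(str_trim(raw))) {
    abort_caro("unparsable_name", "Name must be a single non-empty string")
  }
  name <- normalize_name(raw)
  parts <- decompose_name(name)

  stereo <- if (nzchar(parts$stereo)) {
    parse_stereo_items(str_match(parts$stereo, "^\\((.*)\\)$")[1, 2])
  } else empty_stereo()

  acc <- list(dehydro = empty_pairs(), hydro = empty_pairs(),
              subs = empty_subs(), bridges = empty_bridges(),
              skeletal = empty_subs(), suffix = empty_subs())

  if (nzchar(parts$pre)) {
    for (frag in str_split(parts$pre, "-(?=[0-9(])")[[1]]) {
      acc <- add_fragment(acc, frag, suffix_context = FALSE)
    }
  }

  # stem: end groups and fused apo locants
  gm <- str_match(parts$stem, paste0("^(?:([0-9',]+)-)?", stem_regex(), "$"))
  locs_txt <- gm[1, 2]
  ends <- if (!is.na(gm[1, 3])) c(gm[1, 3], gm[1, 4])
          else if (!is.na(gm[1, 5])) c(gm[1, 5], "-")
          else character()
  if (!is.na(gm[1, 6])) {            # fused (di)apocaroten stem
    if (is.na(locs_txt)) {
      abort_caro("unparsable_name",
                 sprintf("'%s' stem requires locants", gm[1, 6]), token = parts$stem)
    }
    locs <- parse_locant_list(locs_txt)
    want <- if (gm[1, 6] == "diapo") 2L else 1L
    if (nrow(locs) != want) {
      abort_caro("locant_count_mismatch",
                 sprintf("'%s' expects %d locant(s), got %d", gm[1, 6], want, nrow(locs)),
                 token = parts$stem)
    }
    acc$skeletal <- bind_rows(acc$skeletal,
                              tibble(pos = locs$pos, primed = locs$primed, keyword = "apo"))
  }

  if (nzchar(parts$post)) {
    for (frag in str_split(parts$post, "-(?=[0-9(])")[[1]]) {
      acc <- add_fragment(acc, frag, suffix_context = TRUE)
    }
  }

  new_parsed_name(stereo = stereo, dehydro = acc$dehydro, hydro = acc$hydro,
                  substituents = acc$subs, bridges = acc$bridges,
                  skeletal = acc$skeletal, suffix = acc$suffix,
                  end_groups = ends, raw_name = raw)
}

# Dispatch one "<locants>-<keyword>" fragment into the accumulator.
add_fragment <- function(acc, frag, suffix_context) {
  lex <- caro_lexicon()
  m <- str_match(frag, "^([0-9',]+)-([a-z][a-z ]*)$")
  if (is.na(m[1, 1])) stop_unknown_keyword(frag)
  locs <- parse_locant_list(m[1, 2])
  word <- m[1, 3]

  keys <- if (suffix_context) {
    c(names(lex$suffixes), names(lex$bridges), names(lex$skeletal),
      names(lex$substituents), names(lex$hydrogenation))
  } else {
    known_base_keywords()
  }
  sp <- split_multiplier(word, keys)
  base <- sp$base

  pairwise_check <- function(per_item) {
    if (nrow(locs) != sp$mult * per_item) {
      if (per_item == 2L && nrow(locs) %% 2L != 0L) {
        abort_caro("odd_locant_count",
                   sprintf("'%s' has an odd locant count (%d)", frag, nrow(locs)),
                   token = frag)
      }
      abort_caro("locant_count_mismatch",
                 sprintf("'%s' expects %d locant(s), got %d",
                         word, sp$mult * per_item, nrow(locs)),
                 token = frag)
    }
  }

  if (base %in% names(lex$hydrogenation)) {
    pairwise_check(1L)  # multiplier counts locants (didehydro = 2 locants)
    if (nrow(locs) %% 2L != 0L) {
      abort_caro("odd_locant_count",
                 sprintf("'%s' has an odd locant count (%d)", frag, nrow(locs)),
                 token = frag)
    }
    pr <- pair_adjacent(locs)
    slot <- if (base == "dehydro") "dehydro" else "hydro"
    acc[[slot]] <- bind_rows(acc[[slot]], pr)
  } else if (base %in% names(lex$bridges) ||
             (suffix_context && base == "olide")) {
    pairwise_check(2L)
    pr <- pair_adjacent(locs)
    acc$bridges <- bind_rows(acc$bridges,
                             tibble(pos1 = pr$pos1, primed1 = pr$primed1,
                                    pos2 = pr$pos2, primed2 = pr$primed2,
                                    kind = base))
  } else if (base %in% names(lex$skeletal)) {
    pairwise_check(1L)
    acc$skeletal <- bind_rows(acc$skeletal,
                              tibble(pos = locs$pos, primed = locs$primed,
                                     keyword = base))
  } else if (suffix_context && base %in% names(lex$suffixes)) {
    pairwise_check(1L)
    acc$suffix <- bind_rows(acc$suffix,
                            tibble(pos = locs$pos, primed = locs$primed,
                                   keyword = lex$suffixes[[base]]$token))
  } else if (base %in% names(lex$substituents)) {
    pairwise_check(1L)
    acc$subs <- bind_rows(acc$subs,
                          tibble(pos = locs$pos, primed = locs$primed,
                                 keyword = lex$substituents[[base]]$token))
  } else {
    stop_unknown_keyword(word)
  }
  acc
}
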