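# Locants: skeleton carbon positions 1-20, optionally primed for the second
# half of the molecule. Internally a locant is a (pos, primed) pair; rendered
# as "5" or "5'".

parse_locant <- function(x) {
  m <- str_match(x, "^([0-9]+)('?)$")
  if (is.na(m[1, 1])) stop_invalid_locant(x)
  pos <- as.integer(m[1, 2])
  if (pos < 1L || pos > 20L) stop_invalid_locant(x)
  list(pos = pos, primed = m[1, 3] == "'")
}

parse_locant_list <- function(x) {
  parts <- str_split(x, ",")[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) stop_invalid_locant(x)
  locs <- lapply(parts, parse_locant)
  tibble(
    pos = vapply(locs, `[[`, integer(1), "pos"),
    primed = vapply(locs, `[[`, logical(1), "primed")
  )
}

render_locant <- function(pos, primed) paste0(pos, ifelse(primed, "'", ""))

# order: unprimed before primed, then ascending position
locant_order <- function(pos, primed) order(primed, pos)

#' Pair a locant list two at a time
#'
#' Hydrogenation prefixes list their locants as a flat sequence that encodes
#' consecutive pairs: `5,6,7,8,5',6'-hexahydro` saturates the 5,6 and 7,8 and
#' 5',6' bonds. Locants are paired in listed order; an odd count is an error,
#' never silently dropped.
#'
#' @param locants A data frame with columns `pos` and `primed` (as returned by
#'   the name tokenizer), or a character vector of locants like `c("5","6")`.
#' @return A tibble with one row per pair: `pos1`, `primed1`, `pos2`, `primed2`.
#' @examples
#' pair_adjacent(c("5", "6", "7", "8", "5'", "6'"))
#' @export
pair_adjacent <- function(locants) {
  if (is.character(locants)) {
    locants <- if (length(locants)) parse_locant_list(paste(locants, collapse = ",")) else
      tibble(pos = integer(), primed = logical())
  }
  n <- nrow(locants)
  if (n %% 2L != 0L) {
    abort_caro("odd_locant_count",
               sprintf("Hydrogenation locants must pair up; got %d locants", n))
  }
  if (n == 0L) return(tibble(pos1 = integer(), primed1 = logical(),
                             pos2 = integer(), primed2 = logical()))
  i <- seq(1L, n, by = 2L)
  tibble(pos1 = locants$pos[i], primed1 = locants$primed[i],
         pos2 = locants$pos[i + 1L], primed2 = locants$primed[i + 1L])
}

#' Expand a multiplied substituent prefix into per-locant keywords
#'
#' Rewrites `3,5'-dihydroxy` as one `(locant, hydroxy)` record per locant,
#' preserving order. The locant count must equal the multiplier.
#'
#' @param locants A data frame with `pos`/`primed` columns or a character
#'   vector of locants.
#' @param prefix The multiplied keyword, e.g. `"dihydroxy"` or `"hydroxy"`.
#' @return A tibble with columns `pos`, `primed`, `keyword` (the base keyword).
#' @examples
#' expand_multiplicative(c("3", "5'"), "dihydroxy")
#' @export
expand_multiplicative <- function(locants, prefix) {
  if (is.character(locants)) {
    locants <- parse_locant_list(paste(locants, collapse = ","))
  }
  sp <- split_multiplier(prefix, known_base_keywords())
  if (nrow(locants) != sp$mult) {
    abort_caro("locant_count_mismatch",
               sprintf("'%s' expects %d locant(s), got %d", prefix, sp$mult, nrow(locants)),
               token = prefix)
  }
  tibble(pos = locants$pos, primed = locants$primed, keyword = sp$base)
}

known_base_keywords <- function() {
  lex <- caro_lexicon()
  c(names(lex$substituents), names(lex$bridges), names(lex$skeletal),
    names(lex$hydrogenation), names(lex$suffixes))
}

# "didehydro" -> list(base = "dehydro", mult = 2); unknown base keywords abort.
split_multiplier <- function(word, lexicon_keys) {
  mults <- mult_prefixes()
  for (mp in names(mults)[order(nchar(names(mults)), decreasing = TRUE)]) {
    if (startsWith(word, mp) && substring(word, nchar(mp) + 1L) %in% lexicon_keys) {
      return(list(base = substring(word, nchar(mp) + 1L), mult = as.integer(mults[[mp]])))
    }
  }
  if (word %in% lexicon_keys) return(list(base = word, mult = 1L))
  stop_unknown_keyword(word)
}
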