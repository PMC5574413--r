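# Positional chemical fingerprints. A fingerprint is a set of element tokens
# ("3-OH", "5,6+H", "(3S)", "beta,beta"); equality is exact token equality,
# so position matters. Each element belongs to one of the 23 modification
# categories; the end-group pair is itself an element.

canonical_tokens <- c("OH", "Methoxy", "Ethanoyloxy", "Glc", "SO4", "al",
                      "COOH", "nor", "apo", "isoprenyl", "geranylgeranyl",
                      "polymer")
canonical_bridges <- c("Epoxy", "seco", "retro", "olide", "cycloadd")

single_token_regex <- function() {
  sprintf("(?i)^([0-9]+)('?)-(%s)$", paste(canonical_tokens, collapse = "|"))
}
bridge_token_regex <- function() {
  sprintf("(?i)^([0-9]+)('?),([0-9]+)('?)-(%s)$",
          paste(canonical_bridges, collapse = "|"))
}
end_token_regex <- function() {
  eg <- paste(end_group_names(), collapse = "|")
  sprintf("^(%s),(%s|-)$", eg, eg)
}

canonical_case <- function(x, canon) canon[match(tolower(x), tolower(canon))]

element_row <- function(payload, category, pos1 = NA_integer_, primed1 = NA,
                        pos2 = NA_integer_, primed2 = NA) {
  tibble(payload = payload, category = category,
         pos1 = as.integer(pos1), primed1 = as.logical(primed1),
         pos2 = as.integer(pos2), primed2 = as.logical(primed2))
}

check_pos <- function(pos, token) {
  if (any(pos < 1L | pos > 20L)) stop_unknown_token(token)
  pos
}

# Parse one element token into its feature row (canonical payload regenerated).
parse_element <- function(tok) {
  tok <- str_trim(tok)
  m <- str_match(tok, "(?i)^\\(([0-9]+)('?)([RSZE])\\)$")
  if (!is.na(m[1, 1])) {
    pos <- check_pos(as.integer(m[1, 2]), tok)
    d <- toupper(m[1, 4])
    cat <- if (d %in% c("R", "S")) "stereoisomer-RS" else "cis-trans-isomerization"
    return(element_row(paste0("(", pos, m[1, 3], d, ")"), cat, pos, m[1, 3] == "'"))
  }
  m <- str_match(tok, "^([0-9]+)('?),([0-9]+)('?)([+-])H$")
  if (!is.na(m[1, 1])) {
    p1 <- check_pos(as.integer(m[1, 2]), tok); p2 <- check_pos(as.integer(m[1, 4]), tok)
    cat <- if (m[1, 6] == "+") "saturation" else "desaturation"
    return(element_row(paste0(p1, m[1, 3], ",", p2, m[1, 5], m[1, 6], "H"),
                       cat, p1, m[1, 3] == "'", p2, m[1, 5] == "'"))
  }
  m <- str_match(tok, bridge_token_regex())
  if (!is.na(m[1, 1])) {
    p1 <- check_pos(as.integer(m[1, 2]), tok); p2 <- check_pos(as.integer(m[1, 4]), tok)
    kind <- canonical_case(m[1, 6], canonical_bridges)
    return(element_row(paste0(p1, m[1, 3], ",", p2, m[1, 5], "-", kind),
                       unname(bridge_category_map()[kind]),
                       p1, m[1, 3] == "'", p2, m[1, 5] == "'"))
  }
  m <- str_match(tok, "^([0-9]+)('?)=O$")
  if (!is.na(m[1, 1])) {
    pos <- check_pos(as.integer(m[1, 2]), tok)
    return(element_row(paste0(pos, m[1, 3], "=O"), "ketolation", pos, m[1, 3] == "'"))
  }
  m <- str_match(tok, single_token_regex())
  if (!is.na(m[1, 1])) {
    pos <- check_pos(as.integer(m[1, 2]), tok)
    kind <- canonical_case(m[1, 4], canonical_tokens)
    return(element_row(paste0(pos, m[1, 3], "-", kind),
                       unname(token_category_map()[kind]), pos, m[1, 3] == "'"))
  }
  m <- str_match(tok, end_token_regex())
  if (!is.na(m[1, 1])) {
    return(element_row(tok, "cyclization-of-end-groups"))
  }
  stop_unknown_token(tok)
}

element_info <- function(payloads) {
  if (length(payloads) == 0L) {
    return(element_row(character(), character())[0, ])
  }
  bind_rows(lapply(payloads, parse_element))
}

#' Modification category of fingerprint elements
#'
#' Maps element tokens to their chemical modification category: `"+H"` is
#' saturation, `"-H"` desaturation, `-OH` hydroxylation, `=O` ketolation,
#' `-al` aldehyde addition, `-COOH` carbonylation, `-Methoxy` alkoxylation,
#' `-Ethanoyloxy` esterification, `-Glc` glycosidation, `-SO4` sulfation,
#' `-Epoxy` epoxidation, R/S descriptors stereoisomer (RS), Z/E descriptors
#' cis/trans isomerization, and the end-group token cyclization of end groups.
#'
#' @param elements Character vector of element tokens (e.g. `"5,6-Epoxy"`).
#' @return Character vector of category names (see
#'   [modification_categories()]).
#' @examples
#' element_category(c("5,6-Epoxy", "1-Methoxy", "(13Z)"))
#' @export
element_category <- function(elements) {
  element_info(elements)$category
}

new_fp <- function(payloads) {
  info <- element_info(payloads)
  info <- info[!duplicated(info$payload), , drop = FALSE]
  if (sum(info$category == "cyclization-of-end-groups") > 1L) {
    abort_caro("unknown_token", "A fingerprint has at most one end-group element")
  }
  structure(canonical_element_order(info)$payload, class = "caro_fp")
}

# order elements by render category order, then unprimed-before-primed and
# ascending locant; the end-group element is last by construction
canonical_element_order <- function(info) {
  ord <- match(info$category, render_category_order())
  o <- order(ord, info$primed1, info$pos1, info$primed2, info$pos2,
             info$payload)
  info[o, , drop = FALSE]
}

#' Assemble the fingerprint of a parsed name
#'
#' Converts every parsed name feature into its positional element: stereo
#' centers to `(3S)`-style descriptors, dehydro/hydro pairs to `-H`/`+H`
#' elements, substituents and principal-group suffixes to locanted tokens,
#' bridges to `a,b-Epoxy`-style elements, apo/nor to skeletal tokens, and the
#' end-group pair to the final element. Mono-apocarotenoids keep the open end
#' as `"-"` (`"beta,-"`); diapocarotenoids carry no end-group element.
#'
#' @param p A `caro_parsed_name`.
#' @return A `caro_fp` object (character vector of canonical element tokens).
#' @examples
#' build_fingerprint(parse_name("(3R)-beta,beta-caroten-3-ol"))
#' @export
build_fingerprint <- function(p) {
  stopifnot(inherits(p, "caro_parsed_name"))
  payloads <- character()
  if (nrow(p$stereo) > 0) {
    payloads <- c(payloads, paste0("(", render_locant(p$stereo$pos, p$stereo$primed),
                                   p$stereo$descriptor, ")"))
  }
  pair_payload <- function(pairs, sep) {
    if (nrow(pairs) == 0L) return(character())
    paste0(render_locant(pairs$pos1, pairs$primed1), ",",
           render_locant(pairs$pos2, pairs$primed2), sep)
  }
  payloads <- c(payloads, pair_payload(p$dehydro_pairs, "-H"),
                pair_payload(p$hydro_pairs, "+H"))
  single_payload <- function(pos, primed, token) {
    if (token == "=O") paste0(render_locant(pos, primed), "=O")
    else paste0(render_locant(pos, primed), "-", token)
  }
  groups <- bind_rows(p$substituents, p$suffix_groups, p$skeletal_ops)
  if (nrow(groups) > 0) {
    payloads <- c(payloads, unlist(Map(single_payload, groups$pos, groups$primed,
                                       groups$keyword)))
  }
  if (nrow(p$bridges) > 0) {
    bridge_tok <- vapply(caro_lexicon()$bridges, function(x) x$token, character(1))
    payloads <- c(payloads, paste0(
      render_locant(p$bridges$pos1, p$bridges$primed1), ",",
      render_locant(p$bridges$pos2, p$bridges$primed2), "-",
      unname(bridge_tok[p$bridges$kind])))
  }
  if (length(p$end_groups) == 2L) {
    payloads <- c(payloads, paste(p$end_groups, collapse = ","))
  }
  new_fp(payloads)
}

#' Render a fingerprint in its canonical printed form
#'
#' Elements are joined by `", "` in a fixed category order (stereo descriptors
#' first, then cis/trans, `-H`, `+H`, the oxygen substituents, bridges,
#' skeletal operations, and the end-group token last); within a category,
#' unprimed locants precede primed ones, ascending. All R/S centers collapse
#' into one parenthesized prefix, Z/E centers into another.
#'
#' @param fp A `caro_fp`, or a character vector of element tokens.
#' @return A single string such as `"(3R), 3-OH, beta,beta"`.
#' @examples
#' canonical_render(parse_fingerprint("3-OH , (3R), beta,beta"))
#' @export
canonical_render <- function(fp) {
  if (!inherits(fp, "caro_fp")) fp <- new_fp(fp)
  info <- canonical_element_order(element_info(unclass(fp)))
  out <- character()
  for (grp in c("stereoisomer-RS", "cis-trans-isomerization")) {
    rows <- info[info$category == grp, , drop = FALSE]
    if (nrow(rows) > 0) {
      inner <- str_match(rows$payload, "^\\((.*)\\)$")[, 2]
      out <- c(out, paste0("(", paste(inner, collapse = ","), ")"))
    }
  }
  rest <- info[!info$category %in% c("stereoisomer-RS", "cis-trans-isomerization"), ,
               drop = FALSE]
  paste(c(out, rest$payload), collapse = ", ")
}

#' Parse a fingerprint string
#'
#' Inverse of [canonical_render()]; tolerant of the typographic variants the
#' literature prints (Unicode primes, en-dash `–H`, `"4 = O"` spacing).
#' Combined stereo prefixes like `(3S,5R,6S)` expand to per-center elements.
#'
#' @param s A comma-separated fingerprint string.
#' @return A `caro_fp` object.
#' @examples
#' parse_fingerprint("7,8+H, psi,psi")
#' @export
parse_fingerprint <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(str_trim(s))) {
    stop_unknown_token(if (is.character(s) && length(s) == 1L) s else "")
  }
  s <- normalize_chars(s)
  payloads <- character()
  # expand parenthesized stereo groups first
  parens <- str_match_all(s, "\\(([^)]*)\\)")[[1]]
  if (nrow(parens) > 0) {
    for (inner in parens[, 2]) {
      items <- str_trim(str_split(inner, ",")[[1]])
      payloads <- c(payloads, paste0("(", items[nzchar(items)], ")"))
    }
    s <- str_replace_all(s, "\\([^)]*\\)", "")
  }
  frags <- str_trim(str_split(s, ",")[[1]])
  frags <- frags[nzchar(frags)]
  held <- NULL
  eg <- end_group_names()
  for (frag in frags) {
    if (!is.null(held)) {
      frag <- paste0(held, ",", frag)
      held <- NULL
    }
    if (str_detect(frag, "^[0-9]+'?$") || frag %in% eg) {
      held <- frag
    } else {
      payloads <- c(payloads, frag)
    }
  }
  if (!is.null(held)) stop_unknown_token(held)
  if (length(payloads) == 0L) stop_unknown_token(s)
  new_fp(payloads)
}

#' @export
as.character.caro_fp <- function(x, ...) canonical_render(x)

#' @export
print.caro_fp <- function(x, ...) {
  cat("<carotenoid fingerprint> ", canonical_render(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.caro_fp <- function(x, ...) canonical_render(x)

fp_equal <- function(a, b) setequal(unclass(a), unclass(b))

fp_end_groups <- function(fp) {
  info <- element_info(unclass(fp))
  ends <- info$payload[info$category == "cyclization-of-end-groups"]
  if (length(ends) == 0L) return(character())
  str_split(ends[[1]], ",")[[1]]
}

# drop stereo descriptors (R/S and Z/E); used for isomer extraction and the
# optional stereo-blind similarity
fp_destereo <- function(fp) {
  info <- element_info(unclass(fp))
  keep <- !info$category %in% c("stereoisomer-RS", "cis-trans-isomerization")
  structure(info$payload[keep], class = "caro_fp")
}

#' @exportS3Method generics::tidy
tidy.caro_fp <- function(x, ...) {
  element_info(unclass(x))
}

#' @exportS3Method generics::glance
glance.caro_fp <- function(x, ...) {
  info <- element_info(unclass(x))
  ends <- fp_end_groups(x)
  tibble(
    n_elements = nrow(info),
    n_categories = length(unique(info$category)),
    end_groups = if (length(ends)) paste(ends, collapse = ",") else NA_character_,
    carbon_count = carbon_count_elements(info)
  )
}

#' Derive fingerprints for a table of carotenoid names
#'
#' Tibble-first pipeline verb: parses each IUPAC semi-systematic name and adds
#' the canonical fingerprint string plus the parsed fingerprint as a list
#' column.
#'
#' @param data A data frame with a column of names.
#' @param name Column (tidy-select) holding the names; default `iupac_name`.
#' @return `data` with columns `fingerprint` (canonical string) and `fp`
#'   (list of `caro_fp`) added or replaced.
#' @examples
#' tibble::tibble(iupac_name = "beta,beta-carotene") |> fingerprint_names()
#' @export
fingerprint_names <- function(data, name = "iupac_name") {
  stopifnot(is.data.frame(data))
  nm <- data[[name]]
  fps <- lapply(nm, function(x) build_fingerprint(parse_name(x)))
  data <- as_tibble(data)
  data$fp <- fps
  data$fingerprint <- vapply(fps, canonical_render, character(1))
  data
}
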