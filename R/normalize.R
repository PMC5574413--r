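# Typographic normalization. Literature names and fingerprints arrive with
# Unicode primes, Greek letters, en-dashes and inconsistent spacing around
# '=' and '+' ("4 = O" vs "4=O"); everything internal runs on one ASCII form.

greek_translit <- c(
  "β" = "beta", "ψ" = "psi", "ε" = "epsilon", "ϵ" = "epsilon",
  "φ" = "phi", "ϕ" = "phi", "χ" = "chi", "κ" = "kappa",
  "γ" = "gamma", "ζ" = "zeta"
)

# Character-level normalization shared by the name and fingerprint parsers.
normalize_chars <- function(s) {
  s <- str_replace_all(s, "[′’‘´ʹ]", "'")
  s <- str_replace_all(s, "[–—−]", "-")
  s <- str_replace_all(s, greek_translit)
  s <- str_replace_all(s, "\\s*=\\s*", "=")
  s <- str_replace_all(s, "\\s*\\+\\s*", "+")
  s <- str_replace_all(s, "\\s+", " ")
  str_trim(s)
}

name_keywords_regex <- function() {
  if (is.null(the$kw_regex)) {
    lex <- caro_lexicon()
    kws <- c(names(lex$substituents), names(lex$bridges), names(lex$skeletal),
             names(lex$hydrogenation), "caroten", "carotene",
             unlist(lapply(names(lex$suffixes), function(k) gsub(" ", "\\\\s+", k))),
             end_group_names(), names(mult_prefixes()))
    kws <- kws[order(nchar(kws), decreasing = TRUE)]
    the$kw_regex <- paste0("(?i)(", paste(kws, collapse = "|"), ")")
  }
  the$kw_regex
}

#' Normalize a carotenoid name string
#'
#' Maps Unicode primes and Greek letters to their ASCII forms
#' (`β,β-carotene` becomes `beta,beta-carotene`), en/em dashes to
#' hyphens, removes spaces around `=` and `+`, and lower-cases grammar
#' keywords while leaving stereo descriptors and fingerprint atoms (`O`, `H`)
#' untouched. Idempotent; pure string rewriting with no validation.
#'
#' @param raw Character vector of names (or name fragments).
#' @return Character vector of the same length, normalized.
#' @examples
#' normalize_name("β,β-carotene")
#' normalize_name("4 = O")
#' @export
normalize_name <- function(raw) {
  stopifnot(is.character(raw))
  s <- normalize_chars(raw)
  # lower-case only recognized keywords so "(3S...)" and "=O" keep their case
  s <- str_replace_all(s, name_keywords_regex(), tolower)
  str_replace_all(s, "(?i)oic\\s+acid", "oic acid")
}
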