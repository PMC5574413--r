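# Skeleton carbon accounting. The carotene stem is C40: chain carbons 1-15 and
# 1'-15' plus methyls 16,17 (on C1), 18 (on C5), 19 (on C9), 20 (on C13) and
# their primed mirrors. Apo cleavage retains the named carbon and removes
# everything beyond it toward one end, methyls included; nor removes one
# carbon; isoprenyl attachment adds five.

# carbons removed when cleaving beyond carbon n toward the nearest molecule end
apo_removed_end <- function(n) {
  (n - 1L) + 2L * (n > 1L) + (n > 5L) + (n > 9L) + (n > 13L)
}

# carbons removed when a single apo at unprimed n cleaves off the whole primed
# half plus the unprimed chain beyond n (retinal: 15-apo -> C20)
apo_removed_far <- function(n) {
  20L + (15L - n) + (n < 9L) + (n < 13L)
}

apo_carbons_removed <- function(pos, primed) {
  n_apo <- length(pos)
  if (n_apo == 0L) return(0L)
  removed <- integer(n_apo)
  for (i in seq_len(n_apo)) {
    removed[i] <- if (primed[i] || n_apo >= 2L) {
      apo_removed_end(pos[i])
    } else {
      apo_removed_far(pos[i])
    }
  }
  sum(removed)
}

formula_carbons <- function(formula) {
  m <- str_match(formula, "^C([0-9]+)")
  if (is.na(m[1, 1])) {
    abort_caro("unknown_stem",
               sprintf("Cannot read a carbon count from formula '%s'", formula),
               token = formula)
  }
  as.integer(m[1, 2])
}

#' Count skeleton carbons of a parsed carotenoid name
#'
#' With a molecular formula, counts its C atoms. Otherwise starts from the
#' C40 carotene stem, subtracts the carbons cleaved off by each apo locant
#' (using the retained-skeleton lookup; both ends for diapo), subtracts one
#' per nor, and adds five per isoprenyl substituent. Ester or glycoside
#' carbons are not counted: the result is the skeleton carbon number used for
#' C30/C40/C45/C50 classification, not the formula carbon count.
#'
#' @param p A `caro_parsed_name`.
#' @param formula Optional molecular formula string like `"C40H56O2"`.
#' @return Integer carbon count.
#' @examples
#' carbon_count(parse_name("beta,beta-carotene"))
#' carbon_count(parse_name("8'-apo-beta-caroten-8'-al"))
#' @export
carbon_count <- function(p, formula = NULL) {
  if (!is.null(formula) && !is.na(formula) && nzchar(formula)) {
    return(formula_carbons(formula))
  }
  stopifnot(inherits(p, "caro_parsed_name"))
  skel <- p$skeletal_ops
  apo <- skel[skel$keyword == "apo", , drop = FALSE]
  n <- 40L - apo_carbons_removed(apo$pos, apo$primed)
  n <- n - sum(skel$keyword == "nor")
  lex <- caro_lexicon()
  for (i in seq_len(nrow(p$substituents))) {
    kw <- p$substituents$keyword[i]
    entry <- lex$substituents[[match(kw, vapply(lex$substituents, function(x) x$token,
                                                character(1)))]]
    if (!is.null(entry$carbons)) n <- n + as.integer(entry$carbons)
  }
  n
}

# carbon count from fingerprint elements alone (entries loaded without names)
carbon_count_elements <- function(info) {
  apo <- info[info$category == "apo", , drop = FALSE]
  n <- 40L - apo_carbons_removed(apo$pos1, apo$primed1)
  n <- n - sum(info$category == "nor")
  n + 5L * sum(info$category == "isoprene-polymerization") +
    20L * sum(info$category == "geranylgeranyl-polymerization")
}
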