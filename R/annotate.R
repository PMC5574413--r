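# Hierarchical classification: carbon number class, end groups, and the 14
# structural categories, plus the six rule-based biological-function
# predictions. All rules are decidable from the fingerprint and the carbon
# count alone.

#' The 14 structural carotenoid categories
#'
#' Hydrocarbons through diapocarotenoids, in the reference-row order of the
#' classification table.
#'
#' @return Character vector of length 14.
#' @export
structural_categories <- function() {
  c("Hydrocarbons", "Hydroxycarotenoids", "Epoxycarotenoids", "Aldehydes",
    "Ketones", "Carboxylic-acids", "Apocarotenoids", "Norcarotenoids",
    "Secocarotenoids", "Retrocarotenoids", "Olidecarotenoids",
    "Allenecarotenoids", "Acetylenecarotenoids", "Diapocarotenoids")
}

# Priority for the primary (most-derived) category. Derived from the
# reference rows themselves: every curated example must classify to its own
# row, which requires Olidecarotenoids to outrank the allene/acetylene
# desaturation marks (a lactone bridge on an allenic skeleton is the more
# derived feature). See the methods vignette.
structural_priority <- function() {
  c("Hydrocarbons", "Hydroxycarotenoids", "Epoxycarotenoids", "Aldehydes",
    "Ketones", "Carboxylic-acids", "Apocarotenoids", "Norcarotenoids",
    "Secocarotenoids", "Retrocarotenoids", "Allenecarotenoids",
    "Acetylenecarotenoids", "Olidecarotenoids", "Diapocarotenoids")
}

#' Carbon-number class of a carotenoid
#'
#' Carotenoids fall into C30, C40, C45 and C50 classes by skeleton carbon
#' number. Skeletons truncated by apo cleavage of the C40 stem (and nor
#' eliminations) are reported as `"C40-originated"`; C30 diapocarotenoids
#' (both ends cleaved at symmetric low positions, the bacterial C30 pathway)
#' keep the C30 class.
#'
#' @param n Integer skeleton carbon count (>= 9).
#' @param n_apo Number of apo elements in the fingerprint (0, 1 or 2).
#' @return One of `"C30"`, `"C40"`, `"C45"`, `"C50"`, `"C40-originated"`.
#' @examples
#' carbon_class(40)
#' carbon_class(30, n_apo = 1)
#' @export
carbon_class <- function(n, n_apo = 0L) {
  stopifnot(is.numeric(n), n >= 9)
  if (n == 40L) return("C40")
  if (n == 45L) return("C45")
  if (n == 50L) return("C50")
  if (n == 30L && n_apo != 1L) return("C30")
  if (n < 40L) return("C40-originated")
  NA_character_
}

# element categories that do not by themselves make a carotenoid "modified"
benign_categories <- c("cyclization-of-end-groups", "stereoisomer-RS",
                       "cis-trans-isomerization")

oxygen_categories <- c("hydroxylation", "ketolation", "aldehyde-addition",
                       "carbonylation", "alkoxylation", "esterification",
                       "glycosidation", "sulfation", "epoxidation")

has_desat_at <- function(info, a, b) {
  d <- info[info$category == "desaturation", , drop = FALSE]
  any(d$pos1 == a & d$pos2 == b & d$primed1 == d$primed2)
}

has_epoxy_56_58 <- function(info) {
  e <- info[info$category == "epoxidation", , drop = FALSE]
  any(e$pos1 == 5L & e$pos2 %in% c(6L, 8L) & e$primed1 == e$primed2)
}

#' Structural classification of a fingerprint
#'
#' Applies the membership rules of the 14 structural categories and reports
#' every satisfied category plus the primary (most derived) one: hydrocarbons
#' carry nothing beyond end groups, stereo descriptors and
#' saturation/desaturation; any `-OH` makes a hydroxycarotenoid, `-Epoxy` an
#' epoxycarotenoid, `-al` an aldehyde, `=O` a ketone, `-COOH` (or an olide) a
#' carboxylic acid; `apo`, `nor`, `seco`, `retro`, `olide` mark their own
#' categories; a 6,7 (or 6',7') desaturation marks allenes, 7,8 (or 7',8')
#' acetylenes, and exactly two apo elements a diapocarotenoid.
#'
#' @param fp A `caro_fp` or fingerprint string.
#' @return A list with `primary` (single category name) and `all` (character
#'   vector of satisfied categories in reference-row order).
#' @examples
#' classify_structural("7,8+H, psi,psi")
#' @export
classify_structural <- function(fp) {
  if (is.character(fp) && !inherits(fp, "caro_fp")) fp <- parse_fingerprint(fp)
  info <- element_info(unclass(fp))
  cats <- info$category
  n_apo <- sum(cats == "apo")

  sat <- c(benign_categories, "saturation", "desaturation")
  member <- c(
    "Hydrocarbons"         = all(cats %in% sat),
    "Hydroxycarotenoids"   = "hydroxylation" %in% cats,
    "Epoxycarotenoids"     = "epoxidation" %in% cats,
    "Aldehydes"            = "aldehyde-addition" %in% cats,
    "Ketones"              = "ketolation" %in% cats,
    "Carboxylic-acids"     = any(c("carbonylation", "olide") %in% cats),
    "Apocarotenoids"       = n_apo >= 1L,
    "Norcarotenoids"       = "nor" %in% cats,
    "Secocarotenoids"      = "seco" %in% cats,
    "Retrocarotenoids"     = "retro" %in% cats,
    "Olidecarotenoids"     = "olide" %in% cats,
    "Allenecarotenoids"    = has_desat_at(info, 6L, 7L),
    "Acetylenecarotenoids" = has_desat_at(info, 7L, 8L),
    "Diapocarotenoids"     = n_apo == 2L
  )
  all_cats <- structural_categories()[member[structural_categories()]]
  prio <- structural_priority()
  primary <- prio[max(which(member[prio]))]
  list(primary = primary, all = all_cats)
}

#' Predict the six biological functions from a fingerprint
#'
#' Rule-based predictions: provitamin A requires a chemically unmodified
#' skeleton with a beta end group; membrane stabilizers carry oxygen on both
#' ends (oxygen-bearing elements at unprimed and at primed locants); odorous
#' substances and allelochemicals are oxygen-bearing short skeletons (carbon
#' number strictly below 20); antiproliferative activity requires a 5,6- or
#' 5,8-epoxide (either half) on a beta,beta skeleton; reverse-MDR activity
#' the same epoxide on beta,beta, beta,kappa or beta,epsilon end groups.
#'
#' @param fp A `caro_fp` or fingerprint string.
#' @param n_carbons Skeleton carbon count; derived from the fingerprint when
#'   omitted.
#' @param lenient_provitamin If `TRUE`, saturation/desaturation elements do
#'   not disqualify provitamin A (the strict default treats any skeletal
#'   hydrogenation as a modification).
#' @return One-row tibble of six logicals: `provitamin_A`,
#'   `membrane_stabilizer`, `odorous`, `allelochemical`, `antiproliferative`,
#'   `reverse_MDR`.
#' @examples
#' predict_functions("beta,beta")
#' @export
predict_functions <- function(fp, n_carbons = NULL, lenient_provitamin = FALSE) {
  if (is.character(fp) && !inherits(fp, "caro_fp")) fp <- parse_fingerprint(fp)
  info <- element_info(unclass(fp))
  if (is.null(n_carbons)) n_carbons <- carbon_count_elements(info)
  ends <- sort(fp_end_groups(fp))
  cats <- info$category

  unmodified_ok <- if (lenient_provitamin) {
    c(benign_categories, "saturation", "desaturation")
  } else benign_categories
  provit <- "beta" %in% ends && all(cats %in% unmodified_ok)

  oxy <- info[info$category %in% oxygen_categories, , drop = FALSE]
  oxy_unprimed <- any(!oxy$primed1, na.rm = TRUE) | any(!oxy$primed2, na.rm = TRUE)
  oxy_primed <- any(oxy$primed1, na.rm = TRUE) | any(oxy$primed2, na.rm = TRUE)
  membrane <- isTRUE(oxy_unprimed) && isTRUE(oxy_primed)

  small_oxy <- n_carbons < 20L &&
    any(c("ketolation", "hydroxylation", "aldehyde-addition", "epoxidation") %in% cats)

  epoxy_ring <- has_epoxy_56_58(info)
  antiprolif <- epoxy_ring && identical(ends, c("beta", "beta"))
  mdr_ends <- list(c("beta", "beta"), c("beta", "kappa"), c("beta", "epsilon"))
  mdr <- epoxy_ring && any(vapply(mdr_ends, identical, logical(1), y = ends))

  tibble(provitamin_A = provit, membrane_stabilizer = membrane,
         odorous = small_oxy, allelochemical = small_oxy,
         antiproliferative = antiprolif, reverse_MDR = mdr)
}

#' Classify a table of carotenoid entries
#'
#' Adds the carbon class, the primary structural category and the full set of
#' satisfied categories for every entry.
#'
#' @param data An entries tibble (see [read_entries()]) with an `fp` list
#'   column or a `fingerprint` string column.
#' @return `data` with `carbon_class`, `structural_primary` and
#'   `structural_all` (list column) added.
#' @export
classify_entries <- function(data) {
  data <- ensure_fp(data)
  info_list <- lapply(data$fp, function(f) element_info(unclass(f)))
  n <- if ("carbon_count" %in% names(data)) data$carbon_count else
    vapply(info_list, carbon_count_elements, integer(1))
  cls <- lapply(data$fp, classify_structural)
  data$carbon_class <- unlist(Map(function(nc, info) {
    carbon_class(nc, n_apo = sum(info$category == "apo"))
  }, n, info_list))
  data$structural_primary <- vapply(cls, `[[`, character(1), "primary")
  data$structural_all <- lapply(cls, `[[`, "all")
  data
}

#' Predict biological functions for a table of entries
#'
#' @inheritParams classify_entries
#' @param lenient_provitamin See [predict_functions()].
#' @return `data` with the six logical prediction columns added.
#' @export
predict_entries <- function(data, lenient_provitamin = FALSE) {
  data <- ensure_fp(data)
  n <- if ("carbon_count" %in% names(data)) data$carbon_count else
    vapply(data$fp, function(f) carbon_count_elements(element_info(unclass(f))),
           integer(1))
  preds <- bind_rows(Map(function(f, nc) {
    predict_functions(f, n_carbons = nc, lenient_provitamin = lenient_provitamin)
  }, data$fp, n))
  dplyr::bind_cols(data, preds)
}

# ensure an `fp` list column exists, parsing the `fingerprint` strings if not
ensure_fp <- function(data) {
  stopifnot(is.data.frame(data))
  data <- as_tibble(data)
  if (!"fp" %in% names(data)) {
    if (!"fingerprint" %in% names(data)) {
      abort_caro("schema_error", "Need an 'fp' or 'fingerprint' column")
    }
    data$fp <- lapply(data$fingerprint, parse_fingerprint)
  }
  data
}
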