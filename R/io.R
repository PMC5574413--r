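# Readers for entry tables (TSV/JSON) and accessors for the packaged
# reference fixture: the curated example carotenoids (accession, trivial
# name, IUPAC name where known, printed fingerprint, formula, reference
# structural category), four profiled organisms, and the domain-of-life
# presence lists.

entry_columns <- c("accession", "trivial_name", "iupac_name", "fingerprint",
                   "formula", "category", "source_organisms")

#' Load carotenoid entries from TSV or JSON
#'
#' Requires `accession` and `trivial_name` columns plus at least one of
#' `iupac_name` / `fingerprint`. Fingerprint strings are parsed (typographic
#' variants tolerated); rows whose fingerprint or name fails to parse are
#' reported with their line numbers and the load fails atomically. Entries
#' with a name but no fingerprint get one derived from the name.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"json"`; inferred from the extension by default.
#' @return An entries tibble with an `fp` list column, canonical
#'   `fingerprint` strings and a `carbon_count` column (from the formula when
#'   present, else from the fingerprint skeleton).
#' @examples
#' read_entries(system.file("extdata", "entries.tsv", package = "carofp"))
#' @export
read_entries <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (!file.exists(path)) {
    abort_caro("schema_error", sprintf("No such file: %s", path))
  }
  df <- if (format == "tsv") {
    tab <- tryCatch(
      read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                 check.names = FALSE, colClasses = "character"),
      error = function(e) abort_caro("schema_error",
                                     sprintf("Cannot read '%s': %s", path,
                                             conditionMessage(e))))
    as_tibble(tab)
  } else {
    as_tibble(jsonlite::fromJSON(path))
  }
  if (nrow(df) == 0L || !all(c("accession", "trivial_name") %in% names(df))) {
    abort_caro("schema_error",
               "Entries need at least 'accession' and 'trivial_name' columns and one row")
  }
  if (!any(c("iupac_name", "fingerprint") %in% names(df))) {
    abort_caro("schema_error", "Entries need an 'iupac_name' or 'fingerprint' column")
  }
  for (col in setdiff(entry_columns, names(df))) df[[col]] <- NA_character_
  df[df == ""] <- NA

  errors <- character()
  fps <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header line is line 1
    res <- tryCatch({
      if (!is.na(df$fingerprint[i])) {
        parse_fingerprint(df$fingerprint[i])
      } else if (!is.na(df$iupac_name[i])) {
        build_fingerprint(parse_name(df$iupac_name[i]))
      } else {
        abort_caro("schema_error", "Row has neither fingerprint nor iupac_name")
      }
    }, caro_error = function(e) e)
    if (inherits(res, "caro_error")) {
      errors <- c(errors, sprintf("line %d (%s): %s", line, df$accession[i],
                                  conditionMessage(res)))
    } else {
      fps[[i]] <- res
    }
  }
  if (length(errors)) {
    abort_caro("unknown_token",
               paste(c(sprintf("%d row(s) failed to load:", length(errors)), errors),
                     collapse = "\n"),
               lines = errors)
  }
  df$fp <- fps
  df$fingerprint <- vapply(fps, canonical_render, character(1))
  df$carbon_count <- vapply(seq_len(nrow(df)), function(i) {
    if (!is.na(df$formula[i])) formula_carbons(df$formula[i]) else
      carbon_count_elements(element_info(unclass(fps[[i]])))
  }, integer(1))
  df
}

#' Write an entries tibble as TSV
#'
#' @param data Entries tibble.
#' @param path Output path (or `""` for stdout).
#' @return `data`, invisibly.
#' @export
write_entries <- function(data, path) {
  out <- as_tibble(data)
  out$fp <- NULL
  write.table(out, file = path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(data)
}

#' Packaged reference entries
#'
#' The curated example set shipped with the package: the fourteen structural
#' reference carotenoids (one per structural category), fucoxanthin,
#' astaxanthin, beta-carotene, zeaxanthin, lycopene, alpha-carotene and
#' (13Z)-beta-carotene, with accessions, printed fingerprints and molecular
#' formulas where the formula carbon count equals the skeleton count.
#'
#' @return An entries tibble (see [read_entries()]).
#' @examples
#' example_entries()
#' @export
example_entries <- function() {
  read_entries(system.file("extdata", "entries.tsv", package = "carofp"))
}

#' Packaged reference organism profiles
#'
#' Four profiled organisms sharing the simple zeaxanthin-type profile
#' (beta-carotene + zeaxanthin): the red alga Cyanidioschyzon merolae, the
#' cyanobacterium Prochlorothrix hollandica PCC 9006, and the glaucophytes
#' Cyanophora paradoxa and Glaucocystis nostochinearum.
#'
#' @return A profiles tibble (see [read_profiles()]).
#' @export
example_profiles <- function() {
  read_profiles(system.file("extdata", "profiles.json", package = "carofp"))
}

#' Packaged domain-of-life presence lists
#'
#' Carotenoids annotated with the domains of life they occur in: the seven
#' hydrocarbons common to all three domains, and the forty-five further
#' carotenoids (including seventeen apocarotenoids) shared between bacteria
#' and eukaryotes.
#'
#' @return A tibble with `name`, `domains` (list column) and `apocarotenoid`.
#' @examples
#' domain_shared_sets(example_domain_lists())
#' @export
example_domain_lists <- function() {
  raw <- jsonlite::fromJSON(
    system.file("extdata", "domain_lists.json", package = "carofp"),
    simplifyVector = FALSE)
  bind_rows(lapply(raw, function(x) {
    tibble(name = x$name, domains = list(unlist(x$domains)),
           apocarotenoid = isTRUE(x$apocarotenoid))
  }))
}

#' Read a category weight file
#'
#' A JSON object mapping modification categories to positive weights.
#'
#' @param path Path to the JSON file.
#' @return Named numeric vector usable as `weights` in [weighted_tanimoto()].
#' @export
read_weights <- function(path) {
  w <- unlist(jsonlite::fromJSON(path))
  if (!is.numeric(w) || is.null(names(w)) || any(!is.finite(w)) || any(w <= 0)) {
    abort_caro("schema_error", "Weights must be a JSON object of positive numbers")
  }
  w
}
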