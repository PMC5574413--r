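# Organism carotenoid profiles: the set of carotenoids reported from one
# organism, with its ranked lineage. Profile similarity is the plain
# (unweighted) Tanimoto / Jaccard coefficient on accession sets.

#' Read organism carotenoid profiles from JSON
#'
#' Expects an array of objects with `name`, `lineage` (array of
#' `[rank, taxon]` pairs, domain first) and `carotenoids` (array of entry
#' accessions).
#'
#' @param path Path to the profiles JSON file.
#' @return A tibble with columns `name`, `domain`, `lineage` (list of
#'   two-column tibbles) and `carotenoids` (list of character vectors).
#' @examples
#' read_profiles(system.file("extdata", "profiles.json", package = "carofp"))
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) {
    abort_caro("schema_error", sprintf("No such file: %s", path))
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!length(raw)) abort_caro("schema_error", "Empty profiles file")
  rows <- lapply(raw, function(p) {
    if (is.null(p$name) || is.null(p$lineage) || is.null(p$carotenoids)) {
      abort_caro("schema_error",
                 "Each profile needs 'name', 'lineage' and 'carotenoids'")
    }
    lin <- tibble(
      rank = vapply(p$lineage, function(x) as.character(x[[1]]), character(1)),
      taxon = vapply(p$lineage, function(x) as.character(x[[2]]), character(1))
    )
    tibble(name = p$name, domain = lin$taxon[1], lineage = list(lin),
           carotenoids = list(unique(unlist(p$carotenoids))))
  })
  bind_rows(rows)
}

profile_set <- function(profiles, who) {
  idx <- match(who, profiles$name)
  if (is.na(idx)) {
    abort_caro("unknown_organism", sprintf("Organism '%s' not in profiles", who),
               token = who)
  }
  set <- profiles$carotenoids[[idx]]
  if (length(set) == 0L) {
    abort_caro("empty_profile", sprintf("Organism '%s' has an empty profile", who))
  }
  set
}

#' Unweighted Tanimoto similarity of two organism profiles
#'
#' `|A intersect B| / |A union B|` over the two carotenoid accession sets.
#'
#' @param profiles A profiles tibble from [read_profiles()] (or with `name`
#'   and `carotenoids` columns).
#' @param a,b Organism names.
#' @return A number in `[0, 1]`.
#' @examples
#' pr <- example_profiles()
#' profile_tanimoto(pr, "Cyanidioschyzon merolae",
#'                  "Prochlorothrix hollandica PCC 9006")
#' @export
profile_tanimoto <- function(profiles, a, b) {
  sa <- profile_set(profiles, a)
  sb <- profile_set(profiles, b)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

#' Rank organisms by profile similarity to a query organism
#'
#' @inheritParams profile_tanimoto
#' @param query Name of the query organism.
#' @param k Maximum number of hits (default all).
#' @return A tibble `rank`, `name`, `domain`, `score`, descending score with
#'   ties broken by name; the query itself is excluded.
#' @examples
#' rank_profiles(example_profiles(), "Cyanidioschyzon merolae")
#' @export
rank_profiles <- function(profiles, query, k = Inf) {
  qset <- profile_set(profiles, query)
  targets <- profiles[profiles$name != query, , drop = FALSE]
  scores <- vapply(targets$carotenoids, function(s) {
    length(intersect(qset, s)) / length(union(qset, s))
  }, numeric(1))
  out <- tibble(name = targets$name,
                domain = if ("domain" %in% names(targets)) targets$domain
                         else NA_character_,
                score = scores)
  out <- arrange(out, desc(.data$score), .data$name)
  out <- slice_head(out, n = if (is.finite(k)) as.integer(k) else nrow(out))
  mutate(out, rank = row_number(), .before = 1)
}

#' Union of carotenoid sets over a taxon
#'
#' Rolls the profiles up a lineage: the union of the carotenoid sets of every
#' organism whose lineage contains the given rank/taxon pair.
#'
#' @inheritParams profile_tanimoto
#' @param rank Lineage rank, e.g. `"domain"`, `"phylum"`, `"genus"`.
#' @param taxon Taxon name at that rank.
#' @return Sorted character vector of accessions.
#' @examples
#' lineage_rollup(example_profiles(), "domain", "Eukaryotes")
#' @export
lineage_rollup <- function(profiles, rank, taxon) {
  hit <- vapply(profiles$lineage, function(lin) {
    any(lin$rank == rank & lin$taxon == taxon)
  }, logical(1))
  if (!any(hit)) {
    abort_caro("unknown_taxon", sprintf("No profile with %s '%s'", rank, taxon),
               token = taxon)
  }
  sort(unique(unlist(profiles$carotenoids[hit])))
}

#' Shared and unique carotenoid sets across the three domains of life
#'
#' Partitions the carotenoids into the seven Venn regions of the
#' Archaea/Bacteria/Eukaryotes presence sets and derives the pairwise shared
#' totals (e.g. total shared between bacteria and eukaryotes = three-way
#' common + bacteria-eukaryotes-only).
#'
#' @param data A tibble with a `name` (or `accession`) column and either a
#'   `domains` list column of domain names per carotenoid, or logical columns
#'   `Archaea`, `Bacteria`, `Eukaryotes`.
#' @return A `caro_domain_stats` object; see [tidy()] for the region table
#'   and [glance()] for the headline counts.
#' @examples
#' domain_shared_sets(example_domain_lists())
#' @export
domain_shared_sets <- function(data) {
  stopifnot(is.data.frame(data))
  key <- if ("name" %in% names(data)) data$name else data$accession
  if (is.null(key)) abort_caro("schema_error", "Need a 'name' or 'accession' column")
  domains <- c("Archaea", "Bacteria", "Eukaryotes")
  pres <- if ("domains" %in% names(data)) {
    vapply(domains, function(d) {
      vapply(data$domains, function(x) d %in% x, logical(1))
    }, logical(nrow(data)))
  } else if (all(domains %in% names(data))) {
    as.matrix(data[domains]) > 0
  } else {
    abort_caro("schema_error",
               "Need a 'domains' list column or Archaea/Bacteria/Eukaryotes columns")
  }
  pres <- matrix(pres, ncol = 3L, dimnames = list(NULL, domains))

  region_of <- function(a, b, e) {
    paste0(ifelse(a, "A", ""), ifelse(b, "B", ""), ifelse(e, "E", ""))
  }
  reg <- region_of(pres[, 1], pres[, 2], pres[, 3])
  keep <- reg != ""
  regions <- c("A", "B", "E", "AB", "AE", "BE", "ABE")
  members <- lapply(regions, function(r) sort(unique(key[keep][reg[keep] == r])))
  names(members) <- regions

  structure(
    list(
      sets = lapply(domains, function(d) sort(unique(key[pres[, d]]))) |>
        setNames(domains),
      regions = tibble(region = regions,
                       n = vapply(members, length, integer(1)),
                       members = unname(members)),
      pairwise = tibble(
        pair = c("Archaea-Bacteria", "Archaea-Eukaryotes", "Bacteria-Eukaryotes"),
        shared_total = c(
          length(members$AB) + length(members$ABE),
          length(members$AE) + length(members$ABE),
          length(members$BE) + length(members$ABE)
        )
      )
    ),
    class = "caro_domain_stats"
  )
}

#' @export
print.caro_domain_stats <- function(x, ...) {
  cat("<domain-of-life carotenoid set statistics>\n")
  print(x$regions[c("region", "n")])
  print(x$pairwise)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.caro_domain_stats <- function(x, ...) x$regions

#' @exportS3Method generics::glance
glance.caro_domain_stats <- function(x, ...) {
  n <- setNames(x$regions$n, x$regions$region)
  tibble(
    n_total = sum(n),
    archaea_only = n[["A"]], bacteria_only = n[["B"]], eukaryotes_only = n[["E"]],
    three_way_common = n[["ABE"]],
    shared_archaea_bacteria = x$pairwise$shared_total[1],
    shared_archaea_eukaryotes = x$pairwise$shared_total[2],
    shared_bacteria_eukaryotes = x$pairwise$shared_total[3]
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.caro_domain_stats <- function(object, ...) {
  df <- object$regions
  df$region <- factor(df$region, levels = df$region)
  ggplot(df, aes(x = .data$region, y = .data$n)) +
    geom_col() +
    labs(x = "Venn region (A = Archaea, B = Bacteria, E = Eukaryotes)",
         y = "carotenoids",
         title = "Unique and shared carotenoids across the domains of life")
}

#' Structural and stereo isomers of an entry
#'
#' Same molecular formula and identical fingerprints after removing stereo
#' descriptors (R/S and Z/E) means stereoisomers; same formula with differing
#' de-stereoized fingerprints means structural isomers. End-group elements
#' are retained in both comparisons, so alpha- and beta-carotene come out as
#' structural isomers.
#'
#' @param data Entries tibble with `accession`, `formula` and
#'   `fp`/`fingerprint` columns.
#' @param accession Query accession; must carry a formula.
#' @return Tibble of `accession`, `trivial_name`, `relation`
#'   (`"stereo"`/`"structural"`); the query itself is excluded.
#' @examples
#' find_isomers(example_entries(), "CA00309")
#' @export
find_isomers <- function(data, accession) {
  data <- ensure_fp(data)
  idx <- match(accession, data$accession)
  if (is.na(idx)) {
    abort_caro("unknown_accession", sprintf("Accession '%s' not in entries", accession),
               token = accession)
  }
  if (!"formula" %in% names(data) || is.na(data$formula[idx]) ||
      !nzchar(data$formula[idx])) {
    abort_caro("missing_formula",
               sprintf("Entry '%s' has no molecular formula", accession))
  }
  qf <- data$formula[idx]
  qcore <- sort(unclass(fp_destereo(data$fp[[idx]])))
  cand <- data[-idx, , drop = FALSE]
  cand <- cand[!is.na(cand$formula) & cand$formula == qf, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(tibble(accession = character(), trivial_name = character(),
                  relation = character()))
  }
  rel <- vapply(cand$fp, function(f) {
    if (identical(sort(unclass(fp_destereo(f))), qcore)) "stereo" else "structural"
  }, character(1))
  tibble(accession = cand$accession,
         trivial_name = if ("trivial_name" %in% names(cand)) cand$trivial_name
                        else NA_character_,
         relation = rel)
}

lineage_taxon_at <- function(lineage, rank) {
  hit <- lineage$taxon[lineage$rank == rank]
  if (length(hit)) hit[1] else NA_character_
}

#' End group x carbon class x phylum contingency
#'
#' For each combination of carbon class and end-group pair, lists the phyla
#' whose profiled organisms possess at least one such carotenoid.
#'
#' @param entries Entries tibble (`accession`, `fp`/`fingerprint`).
#' @param profiles Profiles tibble from [read_profiles()].
#' @return Long tibble with one row per (`carbon_class`, `end_groups`,
#'   `phylum`).
#' @examples
#' endgroup_carbon_table(example_entries(), example_profiles())
#' @export
endgroup_carbon_table <- function(entries, profiles) {
  entries <- classify_entries(ensure_fp(entries))
  if (nrow(profiles) == 0L) {
    return(tibble(carbon_class = character(), end_groups = character(),
                  phylum = character()))
  }
  ends <- vapply(entries$fp, function(f) {
    e <- fp_end_groups(f)
    if (length(e)) paste(e, collapse = ",") else "no end group"
  }, character(1))
  lut <- tibble(accession = entries$accession, carbon_class = entries$carbon_class,
                end_groups = ends)
  rows <- bind_rows(Map(function(lin, cars) {
    tibble(phylum = lineage_taxon_at(lin, "phylum"), accession = cars)
  }, profiles$lineage, profiles$carotenoids))
  out <- left_join(rows, lut, by = "accession")
  out <- out[!is.na(out$carbon_class), , drop = FALSE]
  distinct(select(out, "carbon_class", "end_groups", "phylum")) |>
    arrange(.data$carbon_class, .data$end_groups, .data$phylum)
}
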