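# Weighted Tanimoto similarity over positional fingerprints. With Q and E the
# element sets of query and entry and W a per-category weight,
#   score(Q, E) = W(Q intersect E) / W(Q union E),
# where W(S) sums the category weights of the elements of S. Category weights
# default to uniform; compute_weights() estimates them inversely proportional
# to category occurrence, down-weighting the very frequent hydroxylation and
# saturation marks.

# accept a caro_fp, a single fingerprint string, or a vector of element tokens
as_caro_fp <- function(x) {
  if (inherits(x, "caro_fp")) return(x)
  if (is.character(x)) {
    if (length(x) == 1L) return(parse_fingerprint(x))
    return(new_fp(x))
  }
  abort_caro("schema_error", "Expected a fingerprint, string or element vector")
}

weights_vector <- function(weights) {
  if (is.null(weights)) {
    return(setNames(rep(1, 23L), modification_categories()))
  }
  if (inherits(weights, "caro_weights") || is.data.frame(weights)) {
    return(setNames(weights$weight, weights$category))
  }
  if (is.numeric(weights) && !is.null(names(weights))) return(weights)
  abort_caro("schema_error", "weights must be NULL, a caro_weights table or a named numeric")
}

#' Weighted Tanimoto similarity of two fingerprints
#'
#' Elements are shared only on exact token equality, so positions matter:
#' `3-OH` and `3'-OH` are different elements. The score is the weight sum over
#' the intersection divided by the weight sum over the union, in `[0, 1]`.
#'
#' @param q,e Fingerprints (`caro_fp` or fingerprint strings).
#' @param weights `NULL` for uniform weights, a [compute_weights()] table, or
#'   a named numeric of category weights.
#' @param include_stereo If `FALSE`, R/S and Z/E elements are dropped from
#'   both fingerprints before comparison.
#' @return A number in `[0, 1]`.
#' @examples
#' weighted_tanimoto("3-OH, beta,beta", "3-OH, 4=O, beta,beta")
#' @export
weighted_tanimoto <- function(q, e, weights = NULL, include_stereo = TRUE) {
  q <- as_caro_fp(q)
  e <- as_caro_fp(e)
  if (!include_stereo) {
    q <- fp_destereo(q)
    e <- fp_destereo(e)
  }
  qs <- unclass(q); es <- unclass(e)
  uni <- union(qs, es)
  if (length(uni) == 0L) {
    abort_caro("empty_fingerprint", "Both fingerprints are empty")
  }
  w <- weights_vector(weights)
  wt <- function(x) {
    cats <- element_category(x)
    miss <- setdiff(unique(cats), names(w))
    if (length(miss)) {
      abort_caro("schema_error",
                 sprintf("No weight for category: %s", paste(miss, collapse = ", ")))
    }
    sum(w[cats])
  }
  wt(intersect(qs, es)) / wt(uni)
}

#' Inverse-occurrence category weights from a fingerprint corpus
#'
#' For each modification category with occurrence count `n_c > 0` across the
#' corpus, the weight is `K / n_c` with `K` chosen so the rarest category gets
#' weight 1; unobserved categories also get weight 1. Very frequent
#' modifications would still dominate the union sums, so the default
#' exceptions clamp hydroxylation and saturation to the minimum computed
#' weight. Named values in `exceptions` override categories directly.
#'
#' @param data An entries tibble (with `fp` or `fingerprint` column), or a
#'   list of fingerprints.
#' @param exceptions Either a character vector of categories to clamp to the
#'   minimum computed weight (default hydroxylation and saturation), or a
#'   named numeric of explicit overrides.
#' @return A `caro_weights` tibble with columns `category`, `n`, `weight`.
#' @examples
#' compute_weights(example_entries())
#' @export
compute_weights <- function(data, exceptions = c("hydroxylation", "saturation")) {
  fps <- if (is.data.frame(data)) ensure_fp(data)$fp else data
  if (length(fps) == 0L) abort_caro("empty_dataset", "No fingerprints to weight")
  cats <- unlist(lapply(fps, function(f) element_category(unclass(f))))
  counts <- table(factor(cats, levels = modification_categories()))
  n <- as.integer(counts)
  observed <- n > 0L
  if (!any(observed)) abort_caro("empty_dataset", "No fingerprint elements in dataset")
  k <- min(n[observed])
  w <- ifelse(observed, k / n, 1)
  names(w) <- modification_categories()
  if (is.numeric(exceptions) && !is.null(names(exceptions))) {
    w[names(exceptions)] <- exceptions
  } else if (is.character(exceptions) && length(exceptions)) {
    w[exceptions[exceptions %in% names(w)]] <- min(w[observed])
  }
  structure(
    tibble(category = modification_categories(), n = n, weight = unname(w)),
    class = c("caro_weights", "tbl_df", "tbl", "data.frame"),
    source = "inverse-frequency"
  )
}

#' @exportS3Method generics::tidy
tidy.caro_weights <- function(x, ...) as_tibble(unclass(x))

#' @exportS3Method ggplot2::autoplot
autoplot.caro_weights <- function(object, ...) {
  df <- as_tibble(unclass(object))
  df$category <- factor(df$category, levels = rev(modification_categories()))
  ggplot(df, aes(x = .data$category, y = .data$weight)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "category weight",
         title = "Inverse-occurrence fingerprint weights")
}

#' Ranked fingerprint similarity search
#'
#' Scores every entry against the query entry with the weighted Tanimoto
#' coefficient and returns the top hits in descending score order, ties broken
#' by ascending accession; the query itself is excluded.
#'
#' @param data An entries tibble with `accession` and `fp`/`fingerprint`
#'   columns.
#' @param query Accession of the query entry (must be present in `data`).
#' @param weights See [weighted_tanimoto()].
#' @param k Maximum number of hits (default all).
#' @param include_stereo See [weighted_tanimoto()].
#' @return A `caro_similarity` tibble: `rank`, `accession`, `trivial_name`
#'   (when present), `score`.
#' @examples
#' rank_similar(example_entries(), "CA00309", k = 5)
#' @export
rank_similar <- function(data, query, weights = NULL, k = Inf,
                         include_stereo = TRUE) {
  data <- ensure_fp(data)
  if (!"accession" %in% names(data)) {
    abort_caro("schema_error", "Entries need an 'accession' column")
  }
  idx <- match(query, data$accession)
  if (is.na(idx)) {
    abort_caro("unknown_accession", sprintf("Accession '%s' not in entries", query),
               token = query)
  }
  qfp <- data$fp[[idx]]
  targets <- data[-idx, , drop = FALSE]
  scores <- vapply(targets$fp, weighted_tanimoto, numeric(1), q = qfp,
                   weights = weights, include_stereo = include_stereo)
  out <- tibble(
    accession = targets$accession,
    trivial_name = if ("trivial_name" %in% names(targets)) targets$trivial_name
                   else NA_character_,
    score = scores
  )
  out <- arrange(out, desc(.data$score), .data$accession)
  out <- slice_head(out, n = if (is.finite(k)) as.integer(k) else nrow(out))
  out <- mutate(out, rank = row_number(), query = query)
  out <- select(out, "rank", "accession", "trivial_name", "score", "query")
  class(out) <- c("caro_similarity", class(out))
  out
}

#' @importFrom dplyr slice_head
#' @exportS3Method ggplot2::autoplot
autoplot.caro_similarity <- function(object, ...) {
  df <- as_tibble(object)
  df$accession <- factor(df$accession, levels = rev(df$accession))
  ggplot(df, aes(x = .data$accession, y = .data$score)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "weighted Tanimoto score",
         title = sprintf("Fingerprints most similar to %s", df$query[1]))
}
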