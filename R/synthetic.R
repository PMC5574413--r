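# Seeded generator of random valid carotenoid parses, names and fingerprints.
# Its purpose is property testing: every generated entry must survive
# parse_name -> build_fingerprint -> canonical_render -> parse_fingerprint
# unchanged. Modification positions are drawn from chemically sensible pools
# (ring substituents at 1-4, hydrogenation along the chain, 5,6/5,8 epoxides)
# but no valence model is enforced.

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sample1 <- function(x) x[sample.int(length(x), 1L)]

random_parsed_name <- function() {
  eg <- end_group_names()
  skeleton <- sample1(c("normal", "normal", "normal", "normal", "monoapo", "diapo"))
  skeletal <- empty_subs()
  ends <- character()
  if (skeleton == "normal") {
    ends <- c(sample1(eg), sample1(eg))
  } else if (skeleton == "monoapo") {
    ends <- c(sample1(eg), "-")
    skeletal <- tibble(pos = sample1(c(4L, 8L, 10L, 12L)), primed = TRUE,
                       keyword = "apo")
  } else {
    p <- sample1(c(4L, 6L, 8L))
    skeletal <- tibble(pos = c(p, p), primed = c(FALSE, TRUE), keyword = "apo")
  }

  stereo <- empty_stereo()
  for (pos in c(3L, 5L, 6L)) {
    for (primed in c(FALSE, TRUE)) {
      if (runif(1) < 0.2) {
        stereo <- bind_rows(stereo, tibble(pos = pos, primed = primed,
                                           descriptor = sample1(c("R", "S"))))
      }
    }
  }
  if (runif(1) < 0.25) {
    stereo <- bind_rows(stereo, tibble(pos = sample1(c(9L, 13L, 15L)),
                                       primed = FALSE, descriptor = "Z"))
  }

  subs <- empty_subs()
  suffix <- empty_subs()
  used <- character()
  place <- function(pos, primed) {
    key <- paste0(pos, primed)
    if (key %in% used) return(FALSE)
    used <<- c(used, key)
    TRUE
  }
  oh_as_suffix <- runif(1) < 0.5
  for (i in seq_len(sample1(0:2))) {
    pos <- sample1(2:4); primed <- runif(1) < 0.5
    if (place(pos, primed)) {
      row <- tibble(pos = pos, primed = primed, keyword = "OH")
      if (oh_as_suffix) suffix <- bind_rows(suffix, row)
      else subs <- bind_rows(subs, row)
    }
  }
  for (i in seq_len(sample1(0:2))) {
    primed <- runif(1) < 0.5
    if (place(4L, primed)) {
      suffix <- bind_rows(suffix, tibble(pos = 4L, primed = primed, keyword = "=O"))
    }
  }
  if (runif(1) < 0.2 && place(1L, FALSE)) {
    subs <- bind_rows(subs, tibble(pos = 1L, primed = FALSE, keyword = "Methoxy"))
  }
  if (runif(1) < 0.1) {
    pos <- sample1(2:3); primed <- runif(1) < 0.5
    if (place(pos, primed)) {
      subs <- bind_rows(subs, tibble(pos = pos, primed = primed,
                                     keyword = sample1(c("Glc", "SO4", "Ethanoyloxy"))))
    }
  }

  hydro <- empty_pairs()
  for (a in c(1L, 5L, 7L)) {
    for (primed in c(FALSE, TRUE)) {
      if (runif(1) < 0.12) {
        hydro <- bind_rows(hydro, tibble(pos1 = a, primed1 = primed,
                                         pos2 = a + 1L, primed2 = primed))
      }
    }
  }
  dehydro <- empty_pairs()
  for (a in c(3L, 6L, 11L)) {
    for (primed in c(FALSE, TRUE)) {
      if (runif(1) < 0.12) {
        dehydro <- bind_rows(dehydro, tibble(pos1 = a, primed1 = primed,
                                             pos2 = a + 1L, primed2 = primed))
      }
    }
  }

  bridges <- empty_bridges()
  if (runif(1) < 0.2) {
    primed <- runif(1) < 0.5
    bridges <- bind_rows(bridges, tibble(pos1 = 5L, primed1 = primed,
                                         pos2 = sample1(c(6L, 8L)), primed2 = primed,
                                         kind = "epoxy"))
  }
  if (runif(1) < 0.05) {
    bridges <- bind_rows(bridges, tibble(pos1 = 19L, primed1 = FALSE,
                                         pos2 = 11L, primed2 = FALSE,
                                         kind = "olide"))
  }
  if (runif(1) < 0.1) {
    skeletal <- bind_rows(skeletal, tibble(pos = 2L, primed = runif(1) < 0.5,
                                           keyword = "nor"))
  }

  new_parsed_name(stereo = stereo, dehydro = dehydro, hydro = hydro,
                  substituents = subs, bridges = bridges, skeletal = skeletal,
                  suffix = suffix, end_groups = ends, raw_name = "")
}

#' Generate synthetic carotenoid entries
#'
#' Deterministic per seed: draws random valid parses (end-group pair, up to
#' eight modifications with non-colliding locants), renders their canonical
#' names and fingerprints, and returns them as an entries tibble. Every
#' generated entry round-trips through the parser.
#'
#' @param n Number of entries (>= 1).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return An entries tibble with `accession`, `trivial_name`, `iupac_name`,
#'   `fingerprint`, `fp` and `carbon_count` columns, plus the parse in the
#'   `parsed` list column.
#' @examples
#' generate_synthetic(3, seed = 42)
#' @export
generate_synthetic <- function(n, seed = 1L) {
  stopifnot(is.numeric(n), n >= 1)
  n <- as.integer(n)
  with_local_seed(seed, {
    parses <- lapply(seq_len(n), function(i) random_parsed_name())
    names_ <- vapply(parses, render_name, character(1))
    parses <- Map(function(p, nm) { p$raw_name <- nm; p }, parses, names_)
    fps <- lapply(parses, build_fingerprint)
    tibble(
      accession = sprintf("SY%05d", seq_len(n)),
      trivial_name = sprintf("synthetic carotenoid %d", seq_len(n)),
      iupac_name = names_,
      fingerprint = vapply(fps, canonical_render, character(1)),
      fp = fps,
      carbon_count = vapply(fps, function(f) {
        carbon_count_elements(element_info(unclass(f)))
      }, integer(1)),
      parsed = parses
    )
  })
}

# order-independent canonical form of a parse, for round-trip equality tests
parsed_signature <- function(p) {
  srt <- function(df) {
    if (!nrow(df)) return(as.data.frame(df))
    as.data.frame(df[do.call(order, as.list(df)), , drop = FALSE],
                  row.names = seq_len(nrow(df)))
  }
  list(stereo = srt(p$stereo), dehydro = srt(p$dehydro_pairs),
       hydro = srt(p$hydro_pairs), substituents = srt(p$substituents),
       bridges = srt(p$bridges), skeletal = srt(p$skeletal_ops),
       suffix = srt(p$suffix_groups), end_groups = p$end_groups)
}
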