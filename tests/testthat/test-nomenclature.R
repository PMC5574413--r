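test_that("normalize_name maps literature typography to the ASCII dialect", {
  expect_equal(normalize_name("β,β-carotene"), "beta,beta-carotene")
  expect_equal(normalize_name("4 = O"), "4=O")
  expect_equal(normalize_name("6′,7′–H"), "6',7'-H")
  expect_equal(normalize_name("5,6 + H"), "5,6+H")
  expect_equal(normalize_name("5,6-Epoxy-3'-Ethanoyloxy"), "5,6-epoxy-3'-ethanoyloxy")
})

test_that("normalize_name is idempotent", {
  cases <- c("β,β-carotene", "4 = O", "6′,7′–H",
             fucoxanthin_name, "(3R)-β,β-caroten-3-ol",
             "8,8'-diapocarotene-8,8'-dial")
  for (s in cases) {
    once <- normalize_name(s)
    expect_identical(normalize_name(once), once)
  }
})

test_that("split_tokens separates locanted fragments, stem and suffix", {
  expect_equal(
    split_tokens(normalize_name(fucoxanthin_name)),
    c("(3S,5R,6S,3'S,5'R,6'R)", "5,6-epoxy", "3'-ethanoyloxy",
      "3,5'-dihydroxy", "6',7'-didehydro", "5,6,7,8,5',6'-hexahydro",
      "beta,beta-caroten", "8-one"))
  expect_equal(split_tokens("beta,beta-carotene"), "beta,beta-caroten")
  expect_equal(split_tokens("(3R)-beta,beta-caroten-3-ol"),
               c("(3R)", "beta,beta-caroten", "3-ol"))
  expect_error(split_tokens("random words"), class = "caro_unparsable_name")
})

test_that("expand_multiplicative rewrites multiplied prefixes per locant", {
  expect_equal(expand_multiplicative(c("3", "5'"), "dihydroxy"),
               tibble::tibble(pos = c(3L, 5L), primed = c(FALSE, TRUE),
                              keyword = "hydroxy"))
  dione <- expand_multiplicative(c("4", "4'"), "dione")
  expect_equal(dione$keyword, c("one", "one"))
  expect_equal(expand_multiplicative("3", "hydroxy")$pos, 3L)
  expect_error(expand_multiplicative(c("3", "4", "5"), "dihydroxy"),
               class = "caro_locant_count_mismatch")
})

test_that("pair_adjacent pairs locants in listed order and rejects odd counts", {
  p <- pair_adjacent(c("5", "6", "7", "8", "5'", "6'"))
  expect_equal(nrow(p), 3L)
  expect_equal(p$pos1, c(5L, 7L, 5L))
  expect_equal(p$pos2, c(6L, 8L, 6L))
  expect_equal(p$primed1, c(FALSE, FALSE, TRUE))
  expect_equal(nrow(pair_adjacent(c("6'", "7'"))), 1L)
  expect_equal(nrow(pair_adjacent(character())), 0L)
  expect_error(pair_adjacent(c("5", "6", "7")), class = "caro_odd_locant_count")
})

test_that("pair_adjacent halves the count and preserves order (property)", {
  withr::with_seed(7, {
    for (i in 1:25) {
      n <- 2L * sample(0:5, 1)
      locs <- paste0(sample(1:15, n, replace = TRUE),
                     ifelse(runif(n) < 0.5, "'", ""))
      p <- pair_adjacent(locs)
      expect_equal(nrow(p), n / 2L)
      flat <- as.vector(rbind(paste0(p$pos1, ifelse(p$primed1, "'", "")),
                              paste0(p$pos2, ifelse(p$primed2, "'", ""))))
      expect_equal(flat, locs)
    }
  })
})

test_that("parse_name captures every feature of the fucoxanthin name", {
  p <- parse_name(fucoxanthin_name)
  expect_equal(p$stereo$pos, c(3L, 5L, 6L, 3L, 5L, 6L))
  expect_equal(p$stereo$descriptor, c("S", "R", "S", "S", "R", "R"))
  expect_equal(p$dehydro_pairs$pos1, 6L)
  expect_true(p$dehydro_pairs$primed1)
  expect_equal(nrow(p$hydro_pairs), 3L)
  expect_setequal(p$substituents$keyword, c("Ethanoyloxy", "OH"))
  expect_equal(p$bridges$kind, "epoxy")
  expect_equal(p$suffix_groups$keyword, "=O")
  expect_equal(p$suffix_groups$pos, 8L)
  expect_equal(p$end_groups, c("beta", "beta"))
})

test_that("parse_name handles trivially simple and heavily modified names", {
  lyc <- parse_name("psi,psi-carotene")
  expect_equal(lyc$end_groups, c("psi", "psi"))
  expect_equal(nrow(lyc$substituents) + nrow(lyc$stereo) + nrow(lyc$bridges) +
                 nrow(lyc$hydro_pairs) + nrow(lyc$dehydro_pairs) +
                 nrow(lyc$skeletal_ops) + nrow(lyc$suffix_groups), 0L)

  act <- parse_name("(3S,3'S)-3,3'-dihydroxy-2,2'-dinor-beta,beta-carotene-4,4'-dione")
  expect_equal(act$stereo$descriptor, c("S", "S"))
  expect_equal(sort(paste0(act$substituents$pos, ifelse(act$substituents$primed, "'", ""))),
               c("3", "3'"))
  expect_equal(act$skeletal_ops$keyword, c("nor", "nor"))
  expect_equal(act$suffix_groups$keyword, c("=O", "=O"))
  expect_equal(act$end_groups, c("beta", "beta"))
})

test_that("parse_name raises classed errors naming the offending token", {
  expect_error(parse_name("no stem here"), class = "caro_unparsable_name")
  err <- tryCatch(parse_name("3-frobnicatoxy-beta,beta-carotene"),
                  caro_unknown_keyword = function(e) e)
  expect_s3_class(err, "caro_unknown_keyword")
  expect_match(conditionMessage(err), "frobnicatoxy")
  expect_error(parse_name("21-hydroxy-beta,beta-carotene"),
               class = "caro_invalid_locant")
  expect_error(parse_name("5,6,7-trihydro-beta,beta-carotene"),
               class = "caro_odd_locant_count")
})

test_that("carbon_count follows the retained-skeleton rules", {
  expect_equal(carbon_count(parse_name("beta,beta-carotene")), 40L)
  # beta-apo-8'-carotenal is C30H40O
  expect_equal(carbon_count(parse_name("8'-apo-beta-caroten-8'-al")), 30L)
  # crocetindial is C20H24O2
  expect_equal(carbon_count(parse_name("8,8'-diapocarotene-8,8'-dial")), 20L)
  # retinal: cleavage at the chain midpoint leaves C20
  expect_equal(carbon_count(parse_name("15-apo-beta-caroten-15-al")), 20L)
  # neurosporaxanthin: C35H46O2
  expect_equal(carbon_count(parse_name("4'-apo-beta-caroten-4'-oic acid")), 35L)
  # nor eliminations subtract one carbon each
  expect_equal(carbon_count(parse_name("2,2'-dinor-beta,beta-carotene")), 38L)
  # a formula short-circuits the lookup
  expect_equal(carbon_count(parse_name("beta,beta-carotene"), formula = "C30H40O"), 30L)
})

test_that("formula carbon counts agree with the skeleton lookup across the fixture", {
  e <- fixture_entries()
  has_formula <- !is.na(e$formula)
  expect_gte(sum(has_formula), 8L)
  for (i in which(has_formula)) {
    from_fp <- carofp:::carbon_count_elements(
      carofp:::element_info(unclass(e$fp[[i]])))
    expect_equal(carofp:::formula_carbons(e$formula[i]), from_fp,
                 label = e$accession[i])
  }
})
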