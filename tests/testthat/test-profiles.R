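test_that("the two printed zeaxanthin-type profiles are identical (score 1)", {
  pr <- fixture_profiles()
  expect_equal(profile_tanimoto(pr, "Cyanidioschyzon merolae",
                                "Prochlorothrix hollandica PCC 9006"), 1)
})

test_that("profile Tanimoto handles partial and disjoint overlaps", {
  toy <- tibble::tibble(
    name = c("a", "b", "c"),
    carotenoids = list("CA00309", c("CA00309", "FX0003"), "FX0004"))
  expect_equal(profile_tanimoto(toy, "a", "b"), 0.5)
  expect_equal(profile_tanimoto(toy, "a", "c"), 0)
  expect_equal(profile_tanimoto(toy, "b", "b"), 1)
  expect_error(profile_tanimoto(toy, "a", "nobody"),
               class = "caro_unknown_organism")
  toy$carotenoids[[1]] <- character()
  expect_error(profile_tanimoto(toy, "a", "b"), class = "caro_empty_profile")
})

test_that("profile symmetry and bounds hold over random profile pairs", {
  withr::with_seed(11, {
    pool <- sprintf("CA%05d", 1:12)
    toy <- tibble::tibble(
      name = paste0("org", 1:10),
      carotenoids = lapply(1:10, function(i) sample(pool, sample(1:6, 1))))
    for (i in 1:9) {
      s <- profile_tanimoto(toy, toy$name[i], toy$name[i + 1])
      expect_equal(s, profile_tanimoto(toy, toy$name[i + 1], toy$name[i]))
      expect_gte(s, 0); expect_lte(s, 1)
      expect_equal(s == 1, setequal(toy$carotenoids[[i]], toy$carotenoids[[i + 1]]))
    }
  })
})

test_that("the glaucophytes and the cyanobacterium all tie at unity", {
  pr <- fixture_profiles()
  res <- rank_profiles(pr, "Cyanidioschyzon merolae")
  expect_equal(nrow(res), 3L)
  expect_equal(res$score, rep(1, 3))
  expect_setequal(res$name, c("Prochlorothrix hollandica PCC 9006",
                              "Cyanophora paradoxa", "Glaucocystis nostochinearum"))
  expect_equal(nrow(rank_profiles(pr, "Cyanidioschyzon merolae", k = 1)), 1L)
})

test_that("lineage roll-ups union carotenoid sets and are rank-monotone", {
  pr <- fixture_profiles()
  expect_equal(lineage_rollup(pr, "domain", "Eukaryotes"),
               c("CA00309", "FX0003"))
  single <- lineage_rollup(pr, "genus", "Prochlorothrix")
  expect_equal(single, sort(pr$carotenoids[[2]]))
  # monotone: a domain contains everything any of its genera contain
  for (g in c("Cyanidioschyzon", "Cyanophora", "Glaucocystis")) {
    expect_true(all(lineage_rollup(pr, "genus", g) %in%
                      lineage_rollup(pr, "domain", "Eukaryotes")))
  }
  expect_error(lineage_rollup(pr, "phylum", "Chordata"),
               class = "caro_unknown_taxon")
})

test_that("domain set statistics reproduce the recorded shared counts", {
  st <- domain_shared_sets(example_domain_lists())
  gl <- glance(st)
  n <- setNames(st$regions$n, st$regions$region)
  expect_equal(n[["BE"]], 45L)   # bacteria share 45 more with eukaryotes
  expect_equal(n[["ABE"]], 7L)   # the seven common hydrocarbons
  expect_equal(gl$shared_bacteria_eukaryotes, 52L)
  expect_equal(gl$shared_archaea_eukaryotes, 7L)
})

test_that("Venn regions partition the union", {
  st <- domain_shared_sets(example_domain_lists())
  all_names <- sort(unique(unlist(st$sets)))
  expect_equal(sum(st$regions$n), length(all_names))
  expect_equal(sort(unlist(st$regions$members)), all_names)
  # single-domain input: every shared region is empty
  solo <- tibble::tibble(name = c("x", "y"),
                         domains = list("Bacteria", "Bacteria"))
  n1 <- setNames(domain_shared_sets(solo)$regions$n,
                 domain_shared_sets(solo)$regions$region)
  expect_equal(unname(n1[c("AB", "AE", "BE", "ABE")]), rep(0L, 4))
})

test_that("isomer extraction separates stereo from structural isomers", {
  e <- fixture_entries()
  iso <- find_isomers(e, "CA00309")  # beta-carotene, C40H56
  expect_false("CA00309" %in% iso$accession)
  expect_equal(iso$relation[iso$accession == "FX0006"], "stereo")       # (13Z)
  expect_equal(iso$relation[iso$accession == "FX0005"], "structural")   # alpha
  expect_equal(iso$relation[iso$accession == "FX0004"], "structural")   # lycopene

  # symmetry: the relation holds from either endpoint
  iso_a <- find_isomers(e, "FX0005")
  expect_equal(iso_a$relation[iso_a$accession == "CA00309"], "structural")
  expect_error(find_isomers(e, "FX0001"), class = "caro_missing_formula")
})

test_that("the end-group x carbon-class table lists the possessing phyla", {
  tab <- endgroup_carbon_table(fixture_entries(), fixture_profiles())
  bb <- tab[tab$carbon_class == "C40" & tab$end_groups == "beta,beta", ]
  expect_setequal(bb$phylum,
                  c("Cyanobacteria", "Rhodophyta", "Glaucocystophyceae"))
  empty <- endgroup_carbon_table(fixture_entries(), fixture_profiles()[0, ])
  expect_equal(nrow(empty), 0L)
})
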