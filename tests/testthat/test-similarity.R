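test_that("weighted Tanimoto: self-similarity is 1, disjoint sets are 0", {
  e <- fixture_entries()
  for (fp in e$fp[1:5]) {
    expect_equal(weighted_tanimoto(fp, fp), 1)
    expect_equal(weighted_tanimoto(fp, fp, weights = compute_weights(e)), 1)
  }
  expect_equal(weighted_tanimoto("psi,psi", "beta,beta"), 0)
})

test_that("astaxanthin vs zeaxanthin scores 3/5 under uniform weights", {
  # |intersection| = {3-OH, 3'-OH, beta,beta} = 3; |union| = 5 (hand count)
  zea <- "(3R,3'R), 3-OH, 3'-OH, beta,beta"
  expect_equal(
    weighted_tanimoto(astaxanthin_fp, zea, include_stereo = FALSE), 3 / 5)
})

test_that("weighted Tanimoto is symmetric and bounded on synthetic pairs", {
  syn <- generate_synthetic(40, seed = 99)
  w <- compute_weights(syn)
  for (i in 1:20) {
    a <- syn$fp[[i]]
    b <- syn$fp[[41L - i]]
    s1 <- weighted_tanimoto(a, b, w)
    expect_equal(s1, weighted_tanimoto(b, a, w))
    expect_gte(s1, 0)
    expect_lte(s1, 1)
    expect_equal(s1 == 1, setequal(unclass(a), unclass(b)))
  }
})

test_that("uniform weights reduce to set Tanimoto (exhaustive subset oracle)", {
  universe <- c("3-OH", "4=O", "5,6-Epoxy", "7,8+H", "1-Methoxy")
  subsets <- lapply(0:31, function(m) universe[bitwAnd(m, 2^(0:4)) > 0])
  for (a in subsets) {
    for (b in subsets) {
      if (length(union(a, b)) == 0L) {
        expect_error(weighted_tanimoto(a, b), class = "caro_empty_fingerprint")
      } else {
        expect_equal(weighted_tanimoto(a, b), set_tanimoto_oracle(a, b))
      }
    }
  }
})

test_that("adding a shared element never decreases the score (monotonicity)", {
  w <- setNames(rep(1, 23), modification_categories())
  w["glycosidation"] <- 0.37
  a <- c("3-OH", "beta,beta")
  b <- c("4=O", "beta,beta")
  base <- weighted_tanimoto(a, b, w)
  expect_gte(weighted_tanimoto(c(a, "2-Glc"), c(b, "2-Glc"), w), base)
  expect_gte(weighted_tanimoto(c(a, "8-al"), c(b, "8-al"), w), base)
})

test_that("compute_weights is inversely proportional to occurrence", {
  # 10 hydroxylation elements vs 5 epoxidation elements -> weights 1:2
  fps <- c(
    lapply(1:5, function(i) parse_fingerprint(sprintf("%d-OH, %d'-OH, beta,beta", i, i))),
    lapply(1:5, function(i) parse_fingerprint(sprintf("%d,%d-Epoxy, beta,beta", i, i + 1))))
  w <- compute_weights(fps, exceptions = character())
  tab <- setNames(w$weight, w$category)
  expect_equal(tab[["epoxidation"]] / tab[["hydroxylation"]], 2)
  # rarest observed category has the maximum weight 1
  expect_equal(max(w$weight[w$n > 0]), 1)

  # uniform limit: equal counts give equal weights
  fps_eq <- lapply(1:4, function(i) parse_fingerprint(sprintf("%d-OH, %d=O", i, i)))
  w_eq <- compute_weights(fps_eq, exceptions = character())
  expect_equal(w_eq$weight[w_eq$category == "hydroxylation"],
               w_eq$weight[w_eq$category == "ketolation"])

  expect_error(compute_weights(list()), class = "caro_empty_dataset")
})

test_that("default exceptions clamp hydroxylation and saturation down", {
  e <- fixture_entries()
  w <- compute_weights(e)
  tab <- setNames(w$weight, w$category)
  expect_lte(tab[["hydroxylation"]], tab[["epoxidation"]])
  expect_lte(tab[["saturation"]], tab[["epoxidation"]])
  n <- setNames(w$n, w$category)
  expect_gt(n[["hydroxylation"]], n[["epoxidation"]])  # OH tokens outnumber Epoxy
})

test_that("rank_similar orders by score then accession and excludes the query", {
  e <- fixture_entries()
  res <- rank_similar(e, "CA00309")
  expect_false("CA00309" %in% res$accession)
  expect_equal(res$score, sort(res$score, decreasing = TRUE))
  expect_equal(nrow(res), nrow(e) - 1L)  # k larger than dataset returns all
  expect_equal(nrow(rank_similar(e, "CA00309", k = 3)), 3L)

  # deterministic tie-break: two targets equidistant from the query
  toy <- tibble::tibble(
    accession = c("Q0001", "B0002", "A0003"),
    trivial_name = c("query", "tie b", "tie a"),
    fingerprint = c("3-OH, beta,beta", "3-OH, 4=O, beta,beta",
                    "3-OH, 4'=O, beta,beta"))
  res <- rank_similar(toy, "Q0001")
  expect_equal(res$score[1], res$score[2])
  expect_equal(res$accession, c("A0003", "B0002"))

  expect_error(rank_similar(e, "CA99999"), class = "caro_unknown_accession")
})
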