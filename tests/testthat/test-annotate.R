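test_that("carbon classes map exact counts and apo-reduced skeletons", {
  expect_equal(carbon_class(40), "C40")
  expect_equal(carbon_class(50), "C50")
  expect_equal(carbon_class(45), "C45")
  expect_equal(carbon_class(30), "C30")                 # C30 diapo pathway
  expect_equal(carbon_class(30, n_apo = 1), "C40-originated")
  expect_equal(carbon_class(20, n_apo = 2), "C40-originated")
  expect_equal(carbon_class(38), "C40-originated")      # nor-reduced C40
})

test_that("every reference fingerprint classifies to its own category", {
  e <- fixture_entries()
  ref <- e[!is.na(e$category), ]
  expect_equal(nrow(ref), 14L)
  for (i in seq_len(nrow(ref))) {
    cls <- classify_structural(ref$fp[[i]])
    expect_equal(cls$primary, ref$category[i], label = ref$accession[i])
    expect_true(ref$category[i] %in% cls$all)
  }
})

test_that("classification membership follows the fingerprint features", {
  expect_equal(classify_structural("7,8+H, psi,psi")$primary, "Hydrocarbons")
  neu <- classify_structural("4'-COOH, 4'-apo, beta,psi")
  expect_true(all(c("Carboxylic-acids", "Apocarotenoids") %in% neu$all))
  expect_equal(neu$primary, "Apocarotenoids")
  expect_equal(classify_structural("8-al, 8'-al, 8-apo, 8'-apo")$primary,
               "Diapocarotenoids")
  # allene/acetylene marks work on either half of the molecule
  expect_equal(classify_structural("6',7'-H, beta,beta")$primary,
               "Allenecarotenoids")
  expect_equal(classify_structural("7',8'-H, beta,beta")$primary,
               "Acetylenecarotenoids")
})

test_that("classification is stable under canonical re-rendering", {
  e <- fixture_entries()
  for (i in seq_len(nrow(e))) {
    again <- parse_fingerprint(canonical_render(e$fp[[i]]))
    expect_equal(classify_structural(again), classify_structural(e$fp[[i]]),
                 label = e$accession[i])
  }
})

test_that("the six function rules reproduce the flagship examples", {
  # beta-carotene: unmodified with beta ends -> provitamin A only
  bc <- predict_functions("beta,beta")
  expect_true(bc$provitamin_A)
  expect_false(any(unlist(bc[-1])))

  # fucoxanthin: epoxidized beta,beta skeleton, oxygen on both halves
  fx <- predict_functions(parse_fingerprint(fucoxanthin_fp))
  expect_true(fx$antiproliferative)
  expect_true(fx$reverse_MDR)
  expect_true(fx$membrane_stabilizer)
  expect_false(fx$provitamin_A)

  # astaxanthin: oxygen on both ends, but modified -> not provitamin A
  ax <- predict_functions(astaxanthin_fp)
  expect_true(ax$membrane_stabilizer)
  expect_false(ax$provitamin_A)

  # crocetindial is exactly C20: the odorous rule is strictly < 20
  cd <- predict_functions("8-al, 8'-al, 8-apo, 8'-apo")
  expect_false(cd$odorous)
  # a genuinely short oxygen-bearing skeleton is odorous/allelochemical
  ion <- predict_functions("13=O, 13-apo, beta,-")
  expect_true(ion$odorous)
  expect_true(ion$allelochemical)
})

test_that("epsilon and kappa epoxy skeletons gate reverse MDR but not antiproliferation", {
  mdr_only <- predict_functions("5,6-Epoxy, beta,epsilon")
  expect_true(mdr_only$reverse_MDR)
  expect_false(mdr_only$antiproliferative)
  neither <- predict_functions("5,6-Epoxy, epsilon,epsilon")
  expect_false(neither$reverse_MDR)
})

test_that("prediction invariants hold across synthetic fingerprints", {
  syn <- generate_synthetic(200, seed = 31)
  preds <- predict_entries(syn)
  # antiproliferative implies reverse MDR (beta,beta satisfies both gates)
  expect_true(all(preds$reverse_MDR[preds$antiproliferative]))
  # provitamin A and membrane stabilization are mutually exclusive
  expect_false(any(preds$provitamin_A & preds$membrane_stabilizer))
})

test_that("the lenient provitamin flag admits hydrogenation-only skeletons", {
  dihydro <- "7,8+H, beta,beta"
  expect_false(predict_functions(dihydro)$provitamin_A)
  expect_true(predict_functions(dihydro, lenient_provitamin = TRUE)$provitamin_A)
})

test_that("classify_entries annotates the full table", {
  e <- classify_entries(fixture_entries())
  expect_true(all(c("carbon_class", "structural_primary", "structural_all") %in%
                    names(e)))
  expect_equal(e$carbon_class[e$accession == "CA00309"], "C40")
  expect_equal(e$carbon_class[e$accession == "CA00886"], "C40-originated")
  expect_equal(e$structural_primary[e$accession == "FX0004"], "Hydrocarbons")
})
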