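# Shared fixtures, loaded once per test run.

fixture_entries <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- example_entries()
    cache
  }
})

fixture_profiles <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- example_profiles()
    cache
  }
})

# The worked example: the algal carotenoid fucoxanthin, in the typography the
# literature prints (Unicode primes), and its expected fingerprint in the
# canonical ASCII dialect.
fucoxanthin_name <- paste0(
  "(3S,5R,6S,3′S,5′R,6′R)-5,6-Epoxy-3′-ethanoyloxy-",
  "3,5′-dihydroxy-6′,7′-didehydro-5,6,7,8,5′,6′-",
  "hexahydro-beta,beta-caroten-8-one")

fucoxanthin_fp <- paste0(
  "(3S,5R,6S,3'S,5'R,6'R), 6',7'-H, 5,6+H, 7,8+H, 5',6'+H, ",
  "3-OH, 5'-OH, 3'-Ethanoyloxy, 8=O, 5,6-Epoxy, beta,beta")

astaxanthin_fp <- "3-OH, 3'-OH, 4=O, 4'=O, beta,beta"

# Independent brute-force set-Tanimoto oracle: element-by-element counting,
# no use of the package's weighting machinery.
set_tanimoto_oracle <- function(a, b) {
  inter <- 0L
  uni <- 0L
  for (el in unique(c(a, b))) {
    if (el %in% a && el %in% b) inter <- inter + 1L
    uni <- uni + 1L
  }
  inter / uni
}
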