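# Memoized EYS fixture shared across test files (construction is seeded and
# deterministic, so sharing it is safe).
shared_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- eys_alu_fixture()
      cache <<- list(
        fx = fx,
        ipair = build_alleles(fx$insertion_locus, fx$insertion),
        dpair = build_alleles(fx$deletion_locus, fx$deletion))
    }
    cache
  }
})

TABLE_WT <- c("ATTAGAAGGATACAATGTTTATG", "CATAAACATTGTATCCTTCTAAT")
TABLE_MUT <- c("GAAGGATACAATGTTGGCCGGGC", "GCCCGGCCAACATTGTATCCTTC",
               "ACATTGTATCCTTCTTTTTTTT", "AAAAAAAAGAAGGATACAATGT")
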