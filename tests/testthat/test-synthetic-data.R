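test_that("the EYS fixture reconstructs the published variant anatomy", {
  sf <- shared_fixture()
  fx <- sf$fx

  expect_identical(revcomp(fx$insertion$tsd), "AACATTGTATCCTTC")
  expect_identical(nchar(fx$insertion$tsd), 15L)
  expect_identical(fx$insertion$tail_len, 56L)
  expect_identical(nchar(fx$insertion$body), 282L)
  expect_identical(fx$deletion$del_end - fx$deletion$del_start + 1L, 56358L)

  # component sum: mutant insertion allele is 282 + 56 + 15 longer than WT
  expect_identical(nchar(sf$ipair$mut) - nchar(sf$ipair$wt), 353L)
  # printed junction k-mers are present in the right allele and absent
  # from the other
  expect_true(grepl("GAAGGATACAATGTTGGCCGGGC", sf$ipair$mut, fixed = TRUE))
  expect_true(grepl("ATTAGAAGGATACAATGTTTATG", sf$ipair$wt, fixed = TRUE))
  expect_false(grepl("ATTAGAAGGATACAATGTTTATG", sf$ipair$mut, fixed = TRUE))
  expect_false(grepl("GAAGGATACAATGTTGGCCGGGC", sf$ipair$wt, fixed = TRUE))
})

test_that("coordinate conversion round-trips across the locus", {
  locus <- shared_fixture()$fx$insertion_locus
  pos <- c(1L, 500L, nchar(locus$wt_sequence))
  expect_identical(ref_to_local(locus, local_to_ref(locus, pos)), pos)
  expect_identical(local_to_ref(locus, ref_to_local(locus, 64430524L)), 64430524L)
  expect_error(ref_to_local(locus, 1L), "outside")
})

test_that("build_alleles applies edits and validates the TSD", {
  wt <- strrep("ACGT", 25)
  locus <- locus_config("t", 1L, wt)
  del <- build_alleles(locus, deletion_spec(41, 50))
  expect_identical(nchar(del$mut), 90L)
  expect_identical(del$mut, paste0(substr(wt, 1, 40), substr(wt, 51, 100)))

  empty <- build_alleles(locus, insertion_spec(50, tsd = "", body = "",
                                               tail_len = 0))
  expect_identical(empty$mut, wt)

  expect_error(build_alleles(locus, insertion_spec(50, tsd = "AAAA", body = "C")),
               "TSD")
})

test_that("simulated reads carry truthful op lists", {
  sf <- shared_fixture()
  # homozygous reference: all reads are pure matches
  r0 <- simulate_reads(sf$ipair, "ref/ref", depth = 3, read_len = 100,
                       error_rate = 0, seed = 11)
  expect_true(all(r0$cigar == "100M"))
  ia <- sf$ipair$insert_after_local
  wt <- sf$ipair$wt
  ok <- vapply(seq_len(nrow(r0)), function(i) {
    loc <- ref_to_local(sf$fx$insertion_locus, r0$mapped_start[i])
    substr(wt, loc, loc + 99L) == r0$sequence[i]
  }, TRUE)
  expect_true(all(ok))

  # long reads spanning the whole insert carry a single I op of full length
  rl <- simulate_reads(sf$ipair, "ref/mut", depth = 20, read_len = 1000,
                       seed = 12, mode = "long")
  ins_ops <- grep("353I", rl$cigar, value = TRUE)
  expect_gt(length(ins_ops), 0)

  # short reads crossing one junction are soft-clipped with insert-matching
  # clipped bases
  rs <- simulate_reads(sf$ipair, "ref/mut", depth = 30, read_len = 100,
                       seed = 13, mode = "short")
  right_clips <- rs[grepl("^\\d+M\\d+S$", rs$cigar), ]
  expect_gt(nrow(right_clips), 0)
  pref_ok <- vapply(seq_len(nrow(right_clips)), function(i) {
    ops <- cigar_ops(right_clips$cigar[i])
    clip <- substr(right_clips$sequence[i], ops$len[1] + 1L,
                   ops$len[1] + ops$len[2])
    startsWith(sf$ipair$insert_seq, clip)
  }, TRUE)
  expect_true(all(pref_ok))

  # op conservation: query-consuming ops sum to the read length, everywhere
  for (r in list(r0, rl, rs)) {
    w <- vapply(r$cigar, function(cg) {
      ops <- cigar_ops(cg)
      sum(ops$len[ops$kind %in% c("M", "I", "S")])
    }, 1L, USE.NAMES = FALSE)
    expect_true(all(w == nchar(r$sequence)))
  }
})

test_that("deletion-spanning reads carry the full-length D op", {
  sf <- shared_fixture()
  rd <- simulate_reads(sf$dpair, "mut/mut", depth = 40, read_len = 1200,
                       seed = 14, mode = "long")
  d <- grep("D", rd$cigar, value = TRUE)
  expect_gt(length(d), 0)
  expect_true(all(grepl("56358D", d)))
})

test_that("seeded simulation is byte-identical and seeds differ", {
  sf <- shared_fixture()
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(sf$ipair, "ref/mut", depth = 5, seed = 42), f1)
  write_fastq(simulate_reads(sf$ipair, "ref/mut", depth = 5, seed = 42), f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(sf$ipair, "ref/mut", depth = 5, seed = 43), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("cohort simulation writes one file per sample and a true truth table", {
  sf <- shared_fixture()
  dir <- withr::local_tempdir()
  gts <- rep("ref/ref", 20); gts[c(3, 15)] <- "ref/mut"
  truth <- simulate_cohort(gts, sf$ipair, dir, depth = 2, seed = 9)
  expect_identical(nrow(truth), 20L)
  expect_true(all(file.exists(truth$file)))
  expect_identical(sum(truth$genotype != "ref/ref"), 2L)
  expect_identical(which(truth$genotype == "ref/mut"), c(3L, 15L))
  reread <- read.table(file.path(dir, "truth.tsv"), header = TRUE, sep = "\t")
  expect_identical(reread$genotype, truth$genotype)
})

test_that("STR family simulation plants a recoverable shared haplotype", {
  sim <- simulate_str_families(seed = 21)
  carriers <- sim$genotypes[sim$genotypes$carrier, ]
  for (m in c("D6S1658", "D6S1026", "D6S1670")) {
    sets <- strsplit(carriers[[m]], "/", fixed = TRUE)
    expect_gt(length(Reduce(intersect, sets)), 0)
  }
  # deterministic under a fixed seed
  sim2 <- simulate_str_families(seed = 21)
  expect_identical(sim$genotypes, sim2$genotypes)
  # empty shared set forces nothing
  free <- simulate_str_families(shared_markers = character(0), seed = 22)
  expect_identical(nrow(free$genotypes), nrow(sim$genotypes))
})
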