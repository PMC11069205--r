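test_that("detect_tsd matches the exhaustive suffix/prefix oracle", {
  withr::local_seed(31)
  for (i in 1:25) {
    tsd_len <- sample(5:20, 1)
    left <- random_seq(80); right <- random_seq(80)
    tsd <- substring(left, 81 - tsd_len)
    insert <- paste0(random_seq(280), tsd)   # TSD copy at the insert 3' end
    call <- insertion_call(1000, insert, left, right)
    got <- detect_tsd(call)
    exp_len <- oracle_tsd_len(insert, left, right, 5, 50)
    expect_identical(got$len, exp_len)
    expect_identical(got$sequence, substring(insert, nchar(insert) - exp_len + 1))
  }
})

test_that("detect_tsd returns NULL without a shared string and checks flanks", {
  call <- insertion_call(10, "GGGG", strrep("C", 60), strrep("C", 60))
  expect_null(detect_tsd(call))
  short <- insertion_call(10, "GGGG", "CCC", "CCC")
  expect_error(detect_tsd(short), "flanks")
})

test_that("detect_poly_tail equals the brute-force window oracle", {
  # pure run with two interior interruptions is absorbed at purity 0.9
  s <- paste0("GCGCGG", "AAAAAAAAAA", "G", "AAAAAAAAAA", "C", "AAAAAAAAAA")
  got <- detect_poly_tail(s, "tail", min_len = 10, purity = 0.9)
  expect_identical(got$tail_base, "A")
  expect_identical(got$tail_len, oracle_tail_len(s, "A", 10, 0.9, "tail"))
  expect_identical(got$tail_len, 32L)

  withr::local_seed(32)
  for (i in 1:30) {
    s <- paste0(random_seq(60), paste(sample(c("A", "A", "A", "G"), 40, TRUE),
                                      collapse = ""))
    got <- detect_poly_tail(s, "tail", min_len = 10, purity = 0.8)
    exp <- oracle_tail_len(s, "A", 10, 0.8, "tail")
    if (is.null(got)) expect_identical(exp, 0L) else expect_identical(got$tail_len, exp)
  }
})

test_that("detect_poly_tail rejects non-A/T runs and empty input", {
  expect_null(detect_poly_tail(strrep("G", 40), "tail"))
  expect_error(detect_poly_tail("", "tail"), "empty")
})

test_that("classify_body identifies family, identity and orientation", {
  lib <- default_consensus_library()
  body <- lib$sequence[lib$family == "AluYa5"]

  hit <- classify_body(body)
  expect_identical(hit$family, "AluYa5")
  expect_identical(hit$identity, 1)
  expect_identical(hit$orientation, "plus")

  rc <- classify_body(revcomp(body))
  expect_identical(rc$family, "AluYa5")
  expect_identical(rc$orientation, "minus")
  expect_identical(rc$identity, 1)

  # a body that is an exact prefix of an entry still reaches identity 1
  expect_identical(classify_body(substr(body, 1, 150))$identity, 1)

  # ~10% planted substitutions give ~0.90 identity
  withr::local_seed(33)
  v <- strsplit(body, "")[[1]]
  pos <- sample(length(v), 28)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  mut <- classify_body(paste(v, collapse = ""))
  expect_identical(mut$family, "AluYa5")
  expect_lt(abs(mut$identity - 0.90), 0.03)

  expect_null(classify_body(random_seq(300), min_identity = 0.8))
})

test_that("decomposition of the EYS insertion reports the published anatomy", {
  sf <- shared_fixture()
  call <- as_insertion_call(sf$ipair)
  rep <- decompose_insertion(call)
  expect_identical(rep$body_len, 282L)
  expect_identical(rep$tail_len, 56L)
  expect_identical(rep$tsd_len, 15L)
  expect_identical(rep$tail_base, "A")
  expect_identical(rep$family, "AluYa5")
  expect_identical(rep$body_identity, 1)
  expect_identical(rep$body_orientation, "plus")

  # transcript-strand reporting flips sequences into the published form
  tr <- decompose_insertion(call, params = list(reporting_strand = "minus"))
  expect_identical(tr$tsd_sequence, "AACATTGTATCCTTC")
  expect_identical(tr$tail_base, "T")
  expect_identical(tr$body_orientation, "minus")
  expect_identical(tr$body_len, 282L)
})

test_that("an insert with no TSD or tail is all body", {
  withr::local_seed(34)
  lib <- default_consensus_library()
  body <- substr(lib$sequence[1], 1, 200)
  call <- insertion_call(500, body, random_seq(80), random_seq(80))
  rep <- decompose_insertion(call)
  expect_identical(rep$tsd_len, 0L)
  expect_identical(rep$tail_len, 0L)
  expect_identical(rep$body_len, nchar(body))
})

test_that("decomposition round-trips random canonical specs exactly", {
  for (s in 201:230) {
    ri <- random_insertion_spec(s)
    rep <- decompose_insertion(as_insertion_call(ri$pair))
    expect_identical(rep$tsd_sequence, ri$spec$tsd)
    expect_identical(rep$tail_len, ri$spec$tail_len)
    expect_identical(rep$tail_base, ri$spec$tail_base)
    expect_identical(rep$body_len, nchar(ri$spec$body))
    # partition: the three components tile the insert
    expect_identical(rep$tsd_len + rep$tail_len + rep$body_len,
                     nchar(ri$pair$insert_seq))
    # classification recovers the planted orientation
    expect_identical(rep$body_orientation, ri$spec$body_orientation)
  }
})

test_that("decomposing the reverse-complemented call mirrors the report", {
  for (s in c(301, 302, 303, 304, 305)) {
    ri <- random_insertion_spec(s)
    call <- as_insertion_call(ri$pair)
    fwd <- decompose_insertion(call)
    mir <- decompose_insertion(insertion_call(
      call$ref_position, revcomp(call$insert_sequence),
      left_flank = revcomp(call$right_flank),
      right_flank = revcomp(call$left_flank)))
    expect_identical(mir$tsd_len, fwd$tsd_len)
    expect_identical(mir$tail_len, fwd$tail_len)
    expect_identical(mir$body_len, fwd$body_len)
    flip <- c(A = "T", T = "A")
    expect_identical(mir$tail_base, unname(flip[fwd$tail_base]))
    if (!is.na(fwd$body_orientation))
      expect_identical(mir$body_orientation,
                       setdiff(c("plus", "minus"), fwd$body_orientation))
  }
})

test_that("hgvs_describe follows the g. conventions", {
  expect_identical(hgvs_describe("insertion", 64430524, length = 352),
                   "g.64430524_64430525ins352")
  expect_identical(hgvs_describe("deletion", 64764235, end = 64820592),
                   "g.64764235_64820592del")
  expect_identical(hgvs_describe("deletion", 100, end = 100), "g.100del")
  expect_error(hgvs_describe("deletion", 10, end = 5), "start > end")
})

test_that("coding_consequence counts novel residues before the first stop", {
  r <- coding_consequence("GCT", phase = 0)
  expect_identical(r$aberrant_aa_count, 1L)
  expect_false(r$premature_stop)

  r <- coding_consequence("GCTGCATAAGCT", phase = 0)  # stop at codon 3
  expect_identical(r$aberrant_aa_count, 2L)
  expect_true(r$premature_stop)

  expect_error(coding_consequence("GCN", 0), "non-ACGT")

  # independent oracle: seqinr translation of the EYS insert in transcript
  # orientation across all three phases
  skip_if_not_installed("seqinr")
  sf <- shared_fixture()
  ins_tx <- revcomp(sf$ipair$insert_seq)
  for (phase in 0:2) {
    skip_chr <- (3 - phase) %% 3
    aa <- seqinr::translate(strsplit(substring(ins_tx, skip_chr + 1), "")[[1]])
    stop_at <- which(aa == "*")[1]
    r <- coding_consequence(ins_tx, phase = phase)
    if (is.na(stop_at)) {
      expect_false(r$premature_stop)
    } else {
      expect_true(r$premature_stop)
      expect_identical(r$aberrant_aa_count, stop_at - 1L)
    }
  }
})
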