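# Independent brute-force oracles used across the suite.  These deliberately
# re-derive results by enumeration rather than calling the package's own
# code paths.

rc_chr <- function(x) chartr("ACGT", "TGCA",
                             vapply(strsplit(x, ""), function(v)
                               paste(rev(v), collapse = ""), ""))

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# longest shared string between insert end and flank, by trying every length
oracle_tsd_len <- function(insert, left_flank, right_flank, min_tsd, max_tsd) {
  best3 <- 0L
  for (l in min_tsd:max_tsd)
    if (l <= nchar(insert) &&
        substring(insert, nchar(insert) - l + 1L) ==
        substring(left_flank, nchar(left_flank) - l + 1L)) best3 <- l
  best5 <- 0L
  for (l in min_tsd:max_tsd)
    if (l <= nchar(insert) &&
        substr(insert, 1L, l) == substr(right_flank, 1L, l)) best5 <- l
  max(best3, best5)
}

# best qualifying homopolymer window by explicit enumeration over all
# terminal windows
oracle_tail_len <- function(seq, base, min_len, purity, from = c("tail", "head")) {
  from <- match.arg(from)
  chars <- strsplit(seq, "")[[1]]
  if (from == "tail") chars <- rev(chars)
  best <- 0L
  for (t in seq_along(chars)) {
    win <- chars[1:t]
    if (win[t] == base && mean(win == base) >= purity) best <- t
  }
  if (best >= min_len) best else 0L
}

# naive per-read substring counting over both probe classes
oracle_scan <- function(seqs, probes) {
  mut_p <- probes$sequence[probes$allele_class == "MUT"]
  wt_p <- probes$sequence[probes$allele_class == "WT"]
  hit <- function(s, ps) {
    for (p in ps) if (regexpr(p, s, fixed = TRUE)[1] > 0) return(TRUE)
    FALSE
  }
  m <- vapply(seqs, hit, TRUE, ps = mut_p, USE.NAMES = FALSE)
  w <- vapply(seqs, hit, TRUE, ps = wt_p, USE.NAMES = FALSE)
  list(mut_reads = sum(m & !w), wt_reads = sum(w & !m),
       conflict_reads = sum(m & w), total = length(seqs))
}

# exhaustive phase oracle for two-founder nuclear pedigrees: enumerates all
# founder haplotype assignments (haplotypes coded 0..3 = v1-bit * 2 + v2-bit)
# and all transmissions, independent of the package's recursive search
oracle_phase_enum <- function(ped, geno) {
  founders <- ped$id[is.na(ped$father) & is.na(ped$mother)]
  kids <- setdiff(ped$id, founders)
  stopifnot(length(founders) == 2L)
  copies <- c(absent = 0L, het = 1L, hom = 2L)
  gt <- function(id, v) {
    r <- geno[geno$id == id, v]
    if (length(r) == 0L || is.na(r)) NA_integer_ else copies[[r]]
  }
  ok_geno <- function(id, h1, h2) {
    g1 <- gt(id, "v1"); g2 <- gt(id, "v2")
    (is.na(g1) || (h1 %/% 2L + h2 %/% 2L) == g1) &&
      (is.na(g2) || (h1 %% 2L + h2 %% 2L) == g2)
  }
  focal <- geno$id[!is.na(geno$v1) & geno$v1 == "het" &
                   !is.na(geno$v2) & geno$v2 == "het"]
  seen_cis <- FALSE; seen_trans <- FALSE; consistent <- FALSE
  f1 <- founders[1]; f2 <- founders[2]
  for (a1 in 0:3) for (a2 in 0:3) for (b1 in 0:3) for (b2 in 0:3) {
    if (!ok_geno(f1, a1, a2) || !ok_geno(f2, b1, b2)) next
    hap <- list(); hap[[f1]] <- c(a1, a2); hap[[f2]] <- c(b1, b2)
    n <- length(kids)
    for (tv in seq_len(max(1L, 4L^n)) - 1L) {
      good <- TRUE; hk <- hap
      t <- tv
      for (ki in seq_len(n)) {
        choice <- t %% 4L; t <- t %/% 4L
        row <- ped[ped$id == kids[ki], ]
        hp <- hap[[row$father]][choice %% 2L + 1L]
        hm <- hap[[row$mother]][choice %/% 2L + 1L]
        if (!ok_geno(kids[ki], hp, hm)) { good <- FALSE; break }
        hk[[kids[ki]]] <- c(hp, hm)
      }
      if (!good) next
      consistent <- TRUE
      for (id in focal) {
        h <- hk[[id]]
        if (any(h == 3L)) seen_cis <- TRUE else seen_trans <- TRUE
      }
      if (length(focal) == 0L) { seen_cis <- TRUE; seen_trans <- TRUE }
    }
  }
  phase <- if (!consistent) "unknown"
           else if (seen_trans && !seen_cis) "trans"
           else if (seen_cis && !seen_trans) "cis"
           else "unknown"
  list(phase = phase, conflict = !consistent)
}

# all maximal runs of markers sharing an allele across carriers, by direct
# scanning; returns the run containing the anchor marker (or n = 0)
oracle_shared_run <- function(geno, markers, anchor_position) {
  carriers <- geno[geno$carrier, , drop = FALSE]
  shared <- logical(nrow(markers))
  for (m in seq_len(nrow(markers))) {
    sets <- strsplit(carriers[[markers$name[m]]], "/", fixed = TRUE)
    vals <- sets[[1]]
    for (s in sets[-1]) vals <- vals[vals %in% s]
    shared[m] <- length(vals) > 0L
  }
  anchor <- which.min(abs(markers$position - anchor_position))
  if (!shared[anchor]) return(list(n = 0L))
  lo <- anchor; while (lo > 1L && shared[lo - 1L]) lo <- lo - 1L
  hi <- anchor; while (hi < nrow(markers) && shared[hi + 1L]) hi <- hi + 1L
  list(n = hi - lo + 1L, first = markers$name[lo], last = markers$name[hi],
       length_bp = markers$position[hi] - markers$position[lo])
}

# small aligned_reads constructor for hand-built op lists
make_reads <- function(starts, cigars, seqs, ids = NULL) {
  df <- data.frame(
    read_id = if (is.null(ids)) sprintf("r%02d", seq_along(starts)) else ids,
    sample_id = "T", haplotype = NA_character_,
    mapped_start = as.integer(starts), cigar = cigars, sequence = seqs)
  class(df) <- c("aligned_reads", "data.frame")
  df
}
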