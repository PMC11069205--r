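## Decomposition of an insertion call into TSD + homopolymer tail + element
## body, with family classification, HGVS-style description and coding
## consequence.

#' Construct an insertion call
#'
#' @param ref_position 1-based reference coordinate of the last base before
#'   the insertion.
#' @param insert_sequence The full inserted sequence (plus strand).
#' @param left_flank,right_flank Reference context immediately 5' / 3' of the
#'   insertion point (from the reference, not the mutant allele; >= 50 bp
#'   each recommended).
#' @return An object of class `insertion_call`.
#' @export
insertion_call <- function(ref_position, insert_sequence, left_flank, right_flank) {
  assert_dna(insert_sequence, "insert_sequence")
  assert_dna(left_flank, "left_flank"); assert_dna(right_flank, "right_flank")
  if (!nzchar(insert_sequence)) stop("insert_sequence must be non-empty", call. = FALSE)
  structure(list(ref_position = as.integer(ref_position),
                 insert_sequence = insert_sequence,
                 left_flank = left_flank, right_flank = right_flank),
            class = "insertion_call")
}

#' Derive an insertion call from a built allele pair
#'
#' @param pair An insertion [build_alleles()] result.
#' @param flank Flank length to extract from the wild-type reference.
#' @return An [insertion_call()].
#' @export
as_insertion_call <- function(pair, flank = 100L) {
  stopifnot(inherits(pair, "allele_pair"), pair$kind == "insertion")
  ia <- pair$insert_after_local
  insertion_call(
    ref_position = local_to_ref(pair$locus, ia),
    insert_sequence = pair$insert_seq,
    left_flank = substr1(pair$wt, max(1L, ia - flank + 1L), ia),
    right_flank = substr1(pair$wt, ia + 1L, min(nchar(pair$wt), ia + flank)))
}

## length of the longest exact shared suffix of a and b (capped at max_l)
shared_suffix_len <- function(a, b, max_l) {
  n <- min(nchar(a), nchar(b), max_l)
  l <- 0L
  while (l < n &&
         substr(a, nchar(a) - l, nchar(a) - l) ==
         substr(b, nchar(b) - l, nchar(b) - l)) l <- l + 1L
  l
}

shared_prefix_len <- function(a, b, max_l) {
  n <- min(nchar(a), nchar(b), max_l)
  l <- 0L
  while (l < n && substr(a, l + 1L, l + 1L) == substr(b, l + 1L, l + 1L)) l <- l + 1L
  l
}

#' Detect the target-site duplication of an insertion call
#'
#' Finds the longest exact string shared between the insert end and the
#' adjacent reference flank, testing both placements: the insert *ending*
#' with the string that also ends the 5' reference flank (the usual layout,
#' `three_prime`), and the insert *starting* with the string that also starts
#' the 3' flank (`five_prime`).  The longer placement wins; ties go to the
#' `three_prime` placement.
#'
#' @param call An [insertion_call()].
#' @param min_tsd,max_tsd Minimum / maximum TSD length considered.
#' @return A list with `sequence`, `len` and `placement`, or `NULL` when no
#'   shared string of at least `min_tsd` bases exists.
#' @export
detect_tsd <- function(call, min_tsd = 5L, max_tsd = 50L) {
  if (min_tsd < 3L) stop("min_tsd must be >= 3", call. = FALSE)
  if (nchar(call$left_flank) < max_tsd || nchar(call$right_flank) < max_tsd)
    stop("flanks shorter than max_tsd", call. = FALSE)
  l3 <- shared_suffix_len(call$insert_sequence, call$left_flank, max_tsd)
  l5 <- shared_prefix_len(call$insert_sequence, call$right_flank, max_tsd)
  if (max(l3, l5) < min_tsd) return(NULL)
  if (l3 >= l5)
    list(sequence = substr(call$insert_sequence,
                           nchar(call$insert_sequence) - l3 + 1L,
                           nchar(call$insert_sequence)),
         len = l3, placement = "three_prime")
  else
    list(sequence = substr(call$insert_sequence, 1L, l5),
         len = l5, placement = "five_prime")
}

#' Detect a homopolymer tail
#'
#' Scans from the designated end of `seq` for the longest terminal window
#' whose inner edge is the run base and in which the run base accounts for at
#' least `purity` of the window; the run base is the majority base of the
#' terminal `min_len` bases (ties resolved to the terminal base).
#'
#' @param seq Sequence to scan (typically the insert after TSD removal).
#' @param search_end `"tail"` (3' end) or `"head"` (5' end).
#' @param min_len Minimum reported run length.
#' @param purity Minimum fraction of the run base within the run
#'   (`0.5 < purity <= 1`).
#' @return A list with `tail_base` and `tail_len`, or `NULL` if the best run
#'   is shorter than `min_len`.
#' @export
detect_poly_tail <- function(seq, search_end = c("tail", "head"),
                             min_len = 10L, purity = 0.9) {
  search_end <- match.arg(search_end)
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  if (purity <= 0.5 || purity > 1) stop("purity must be in (0.5, 1]", call. = FALSE)
  if (min_len < 5L) stop("min_len must be >= 5", call. = FALSE)
  chars <- strsplit(seq, "")[[1]]
  if (search_end == "tail") chars <- rev(chars)   # scan inward from the end
  win <- chars[seq_len(min(min_len, length(chars)))]
  tab <- sort(table(win), decreasing = TRUE)
  base <- if (sum(tab == tab[1L]) > 1L && chars[1L] %in%
              names(tab)[tab == tab[1L]]) chars[1L] else names(tab)[1L]
  ## poly-A/T tails only: C/G homopolymers are not retrotransposition tails
  if (!base %in% c("A", "T")) return(NULL)
  best <- 0L; hits <- 0L
  for (i in seq_along(chars)) {
    hits <- hits + (chars[i] == base)
    if (chars[i] == base && hits / i >= purity) best <- i
  }
  if (best < min_len) return(NULL)
  list(tail_base = base, tail_len = best)
}

#' Decompose an insertion into TSD, tail and body
#'
#' Runs TSD detection, homopolymer-tail detection adjacent to the TSD (with
#' fallback to the opposite insert end, where the tail of a minus-orientation
#' element lies), and classifies the remaining body against a consensus
#' library.  Among all exact shared-flank lengths compatible with the winning
#' TSD placement, the TSD length maximizing the detected tail is chosen
#' (ties to the longest TSD): bases shared between the duplication and the
#' homopolymer are conventionally assigned to the tail, which keeps the
#' partition identifiable.
#'
#' @param call An [insertion_call()].
#' @param library Consensus library data.frame.
#' @param params List of tuning parameters; defaults are
#'   `min_tsd = 5`, `max_tsd = 50`, `tail_min_len = 10`, `tail_purity = 0.9`,
#'   `min_identity = 0.8`, `reporting_strand = "plus"`.  With
#'   `reporting_strand = "minus"` all reported sequences are
#'   reverse-complemented (transcript orientation for a minus-strand gene)
#'   and the tail base and body orientation are flipped.
#' @return An object of class `mei_report`: a list with `tsd_sequence`,
#'   `tsd_len`, `tail_base`, `tail_len`, `body_sequence`, `body_len`,
#'   `family`, `body_identity`, `body_orientation`, `hgvs`,
#'   `reporting_strand`.
#' @export
decompose_insertion <- function(call, library = default_consensus_library(),
                                params = list()) {
  p <- modifyList(list(min_tsd = 5L, max_tsd = 50L, tail_min_len = 10L,
                       tail_purity = 0.9, min_identity = 0.8,
                       reporting_strand = "plus"), params)
  ins <- call$insert_sequence
  n <- nchar(ins)
  tsd0 <- detect_tsd(call, p$min_tsd, p$max_tsd)

  tail_for <- function(remainder, adjacent_end) {
    if (!nzchar(remainder)) return(NULL)
    t1 <- detect_poly_tail(remainder, adjacent_end, p$tail_min_len, p$tail_purity)
    if (!is.null(t1)) return(c(t1, list(end = adjacent_end)))
    other <- if (adjacent_end == "tail") "head" else "tail"
    t2 <- detect_poly_tail(remainder, other, p$tail_min_len, p$tail_purity)
    if (!is.null(t2)) c(t2, list(end = other)) else NULL
  }

  tsd_len <- 0L; tsd_seq <- NULL; placement <- NULL; tail <- NULL
  if (!is.null(tsd0)) {
    placement <- tsd0$placement
    tsd_len <- tsd0$len
    ## a boundary base shared by the duplication and the adjacent insert base
    ## is ambiguous; assign it to the tail side (trim the TSD) so that
    ## homopolymer-adjacent duplications keep the conventional annotation
    if (placement == "three_prime") {
      while (tsd_len > p$min_tsd &&
             substr(ins, n - tsd_len + 1L, n - tsd_len + 1L) ==
             substr(ins, n - tsd_len, n - tsd_len))
        tsd_len <- tsd_len - 1L
      tsd_seq <- substr(ins, n - tsd_len + 1L, n)
      tail <- tail_for(substr1(ins, 1L, n - tsd_len), "tail")
    } else {
      while (tsd_len > p$min_tsd &&
             substr(ins, tsd_len, tsd_len) ==
             substr(ins, tsd_len + 1L, tsd_len + 1L))
        tsd_len <- tsd_len - 1L
      tsd_seq <- substr(ins, 1L, tsd_len)
      tail <- tail_for(substr1(ins, tsd_len + 1L, n), "head")
    }
  } else {
    tail <- tail_for(ins, "tail")
  }

  ## body = what remains after stripping TSD and tail
  from <- 1L; to <- n
  if (tsd_len > 0L) {
    if (placement == "three_prime") to <- to - tsd_len else from <- from + tsd_len
  }
  if (!is.null(tail)) {
    if (tail$end == "tail") to <- to - tail$tail_len else from <- from + tail$tail_len
  }
  body <- substr1(ins, from, to)

  cls <- if (nzchar(body)) classify_body(body, library, p$min_identity) else NULL

  rep <- structure(list(
    tsd_sequence = tsd_seq, tsd_len = tsd_len,
    tail_base = if (is.null(tail)) NA_character_ else tail$tail_base,
    tail_len = if (is.null(tail)) 0L else tail$tail_len,
    body_sequence = body, body_len = nchar(body),
    family = if (is.null(cls)) NA_character_ else cls$family,
    body_identity = if (is.null(cls)) NA_real_ else cls$identity,
    body_orientation = if (is.null(cls)) NA_character_ else cls$orientation,
    hgvs = hgvs_describe(kind = "insertion", start = call$ref_position, length = n),
    reporting_strand = "plus"), class = "mei_report")

  if (identical(p$reporting_strand, "minus")) {
    flip <- c(A = "T", C = "G", G = "C", T = "A")
    rep$tsd_sequence <- if (is.null(rep$tsd_sequence)) NULL else revcomp(rep$tsd_sequence)
    if (!is.na(rep$tail_base)) rep$tail_base <- unname(flip[rep$tail_base])
    if (nzchar(rep$body_sequence)) rep$body_sequence <- revcomp(rep$body_sequence)
    if (!is.na(rep$body_orientation))
      rep$body_orientation <- if (rep$body_orientation == "plus") "minus" else "plus"
    rep$reporting_strand <- "minus"
  }
  rep
}

#' HGVS-style description of a simple structural variant
#'
#' Insertions are rendered as `g.<pos>_<pos+1>ins<len>`, deletions as
#' `g.<start>_<end>del` (single-base: `g.<pos>del`).
#'
#' @param kind `"insertion"` or `"deletion"`.
#' @param start For insertions, the last reference base before the insert;
#'   for deletions, the first deleted base.
#' @param end Last deleted base (deletions only).
#' @param length Inserted length (insertions only).
#' @return A character string.
#' @export
hgvs_describe <- function(kind = c("insertion", "deletion"), start, end = NULL,
                          length = NULL) {
  kind <- match.arg(kind)
  start <- as.integer(start)
  if (kind == "insertion") {
    sprintf("g.%d_%dins%d", start, start + 1L, as.integer(length))
  } else {
    end <- as.integer(end)
    if (start > end) stop("start > end", call. = FALSE)
    if (start == end) sprintf("g.%ddel", start)
    else sprintf("g.%d_%ddel", start, end)
  }
}

#' Coding consequence of an in-exon insertion
#'
#' Translates the inserted sequence (in transcript orientation, plus any
#' caller-supplied read-through bases 3' of it) in the reading frame given by
#' the insertion's phase within its codon, and reports how many novel amino
#' acids precede the first stop codon.
#'
#' @param insert_seq Inserted sequence in transcript orientation.
#' @param phase Position of the insertion within its codon (0, 1 or 2): the
#'   number of codon bases already laid down 5' of the insert.  Translation
#'   of the novel frame starts after `(3 - phase) %% 3` bases completing the
#'   interrupted codon are skipped.
#' @param read_through Downstream transcript bases to continue translation
#'   into when the insert itself contains no stop.
#' @return A list with `aberrant_aa_count` (novel residues strictly before
#'   the stop), `premature_stop` (stop within the insert-derived frame) and
#'   `frame_offset`.
#' @export
coding_consequence <- function(insert_seq, phase = 0L, read_through = "") {
  assert_dna(insert_seq, "insert_seq")
  if (nzchar(read_through)) assert_dna(read_through, "read_through")
  if (!phase %in% 0:2) stop("phase must be 0, 1 or 2", call. = FALSE)
  skip <- (3L - as.integer(phase)) %% 3L
  full <- paste0(insert_seq, read_through)
  coding <- substr1(full, skip + 1L, nchar(full))
  n_codon <- nchar(coding) %/% 3L
  aa <- if (n_codon > 0L)
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(coding, 1L, 3L * n_codon)),
      no.init.codon = TRUE))
  else ""
  stop_at <- regexpr("*", aa, fixed = TRUE)[1L]
  premature <- stop_at > 0L &&
    (skip + (stop_at - 1L) * 3L + 1L) <= nchar(insert_seq)
  count <- if (stop_at > 0L) stop_at - 1L else n_codon
  list(aberrant_aa_count = as.integer(count),
       premature_stop = premature,
       frame_offset = as.integer(phase))
}
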