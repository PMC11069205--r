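## Design of allele-diagnostic junction k-mers, specificity checking, and
## grep-style pattern emission.

new_probe_set <- function(df, k) {
  df <- df[!duplicated(df$sequence), , drop = FALSE]
  df$length <- nchar(df$sequence)
  if (!"validated" %in% names(df)) df$validated <- NA
  rownames(df) <- NULL
  structure(df, k = k, class = c("probe_set", "data.frame"))
}

## homopolymer run length adjacent to a junction (pos = last base of left side)
run_left <- function(seq, pos) {
  b <- substr(seq, pos, pos); n <- 0L
  while (pos - n >= 1L && substr(seq, pos - n, pos - n) == b) n <- n + 1L
  n
}
run_right <- function(seq, pos) {
  b <- substr(seq, pos + 1L, pos + 1L); n <- 0L
  len <- nchar(seq)
  while (pos + 1L + n <= len && substr(seq, pos + 1L + n, pos + 1L + n) == b) n <- n + 1L
  n
}

## extract a junction probe: `pos` is the last base of the left side
junction_kmer <- function(seq, pos, left_n, right_n) {
  lo <- max(1L, pos - left_n + 1L)
  hi <- min(nchar(seq), pos + right_n)
  substr(seq, lo, hi)
}

#' Design junction probes for a characterized insertion
#'
#' Emits, for each of the two mutant junctions (reference/insert and
#' insert/reference), the plus-strand k-mer spanning the junction and its
#' reverse complement (4 MUT probes), and the wild-type-site k-mer centered
#' on the insertion point with its reverse complement (2 WT probes).  By
#' default probes are centered (`ceiling(k/2)` bases from the 5' side); when
#' the sequence adjacent to a junction is a homopolymer run at least as long
#' as that side's allocation, that side is capped at `homopolymer_cap` bases
#' and the remainder is taken from the other side (the probe may come out
#' shorter than `k` when the other side is bounded).  Explicit per-side
#' lengths via `sides` override both rules, which allows reproducing
#' published probe layouts verbatim.
#'
#' @param pair An insertion [build_alleles()] result.
#' @param k Design length in nt.
#' @param homopolymer_cap Maximum bases contributed by a homopolymer side.
#' @param sides Optional named list of `c(left, right)` base counts per
#'   junction, e.g. `list(five_prime = c(15, 8))`; junctions not named use
#'   the default rules.
#' @return A `probe_set` data.frame (`sequence`, `allele_class`, `junction`,
#'   `strand`, `length`, `validated`).
#' @export
design_junction_probes <- function(pair, k = 23L, homopolymer_cap = 8L,
                                   sides = list()) {
  stopifnot(inherits(pair, "allele_pair"), pair$kind == "insertion")
  if (k < 12L) stop("k must be >= 12", call. = FALSE)
  ia <- pair$insert_after_local
  L <- nchar(pair$insert_seq)
  if (ia < k || nchar(pair$wt) - ia < k)
    stop("insufficient flank for probe design", call. = FALSE)

  side_lengths <- function(seq, pos, junction) {
    if (!is.null(sides[[junction]])) {
      s <- sides[[junction]]
      return(c(left = s[1L], right = s[2L]))
    }
    left_n <- as.integer(ceiling(k / 2)); right_n <- k - left_n
    if (run_left(seq, pos) >= left_n) {
      left_n <- min(left_n, homopolymer_cap)
      right_n <- k - left_n
    } else if (run_right(seq, pos) >= right_n) {
      right_n <- min(right_n, homopolymer_cap)
      left_n <- k - right_n
    }
    c(left = left_n, right = right_n)
  }
  make <- function(seq, pos, junction, class) {
    sl <- side_lengths(seq, pos, junction)
    fwd <- junction_kmer(seq, pos, sl["left"], sl["right"])
    data.frame(sequence = c(fwd, revcomp(fwd)),
               allele_class = class, junction = junction,
               strand = c("plus", "minus"))
  }
  ## the diagnostic 3' boundary is element|TSD-copy: the TSD copy and the
  ## bases after it are reference-identical, so insert-end|reference k-mers
  ## would match the wild type
  tsd_len <- nchar(pair$variant$tsd)
  probes <- rbind(
    make(pair$mut, ia, "five_prime", "MUT"),
    make(pair$mut, ia + L - tsd_len, "three_prime", "MUT"),
    make(pair$wt, ia, "wt_site", "WT"))
  new_probe_set(probes, k)
}

#' The published EYS AluYa5 screening probes
#'
#' The six probe sequences used to screen short-read data for the EYS exon 43
#' AluYa5 insertion: two chimeric 23-mers at the EYS-Alu junction, a 22-mer
#' pair at the poly-tail junction (the homopolymer side contributes 8 bases),
#' and the two wild-type-site 23-mers, each junction given forward and
#' reverse-complement.
#'
#' @return A `probe_set` data.frame.
#' @export
eys_alu_probe_set <- function() {
  new_probe_set(data.frame(
    sequence = c(EYS_PROBES_MUT, EYS_PROBES_WT),
    allele_class = c(rep("MUT", 4L), rep("WT", 2L)),
    junction = c("five_prime", "five_prime", "three_prime", "three_prime",
                 "wt_site", "wt_site"),
    strand = c("plus", "minus", "minus", "plus", "plus", "minus")),
    k = 23L)
}

occurs <- function(probe, seqs) {
  any(vapply(seqs, function(s)
    grepl(probe, s, fixed = TRUE) || grepl(revcomp(probe), s, fixed = TRUE),
    TRUE, USE.NAMES = FALSE))
}

#' Validate probe specificity against alleles and background
#'
#' A MUT probe validates when it (or its reverse complement) occurs in the
#' mutant allele and occurs in neither the wild-type allele nor any
#' background sequence; a WT probe validates when present in the wild type
#' and absent from the background.  Matching is exact substring on either
#' strand.
#'
#' @param probes A `probe_set` (designed or user-supplied).
#' @param mut_allele,wt_allele Haplotype sequences.
#' @param background Character vector of additional sequences that must not
#'   match (decoy loci etc.).
#' @return The `probe_set` with its `validated` column filled in.
#' @export
check_specificity <- function(probes, mut_allele, wt_allele,
                              background = character()) {
  if (any(grepl("[^ACGT]", probes$sequence)))
    stop("probes must be strict ACGT", call. = FALSE)
  probes$validated <- vapply(seq_len(nrow(probes)), function(i) {
    p <- probes$sequence[i]
    if (probes$allele_class[i] == "MUT")
      occurs(p, mut_allele) && !occurs(p, wt_allele) &&
        (length(background) == 0L || !occurs(p, background))
    else
      occurs(p, wt_allele) &&
        (length(background) == 0L || !occurs(p, background))
  }, TRUE)
  probes
}

#' Emit search patterns for validated probes
#'
#' @param probes A validated `probe_set`.
#' @param dialect `"fastq_grep"` (single backslash-pipe alternation per
#'   allele class, as used with `zgrep -c`), `"sam_grep"` (repeated `-e`
#'   options), or `"plain"` (one sequence per line).
#' @return A named list with one element per allele class present
#'   (`MUT`, `WT`).
#' @export
emit_patterns <- function(probes, dialect = c("fastq_grep", "sam_grep", "plain")) {
  dialect <- match.arg(dialect)
  ok <- probes[!is.na(probes$validated) & probes$validated, , drop = FALSE]
  if (nrow(ok) == 0L) stop("no validated probes", call. = FALSE)
  out <- lapply(split(ok$sequence, ok$allele_class), function(seqs) {
    switch(dialect,
           fastq_grep = paste(seqs, collapse = "\\|"),
           sam_grep = paste0("-e ", seqs, collapse = " "),
           plain = seqs)
  })
  out[order(names(out), decreasing = TRUE)]   # WT first, as in the original layout
}
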