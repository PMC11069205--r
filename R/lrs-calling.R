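## Long-read SV calling: per-read signatures from explicit alignment ops,
## single-linkage clustering into calls, insert consensus polishing, and
## repeat-context annotation of breakpoints.

#' Extract SV signatures from aligned reads
#'
#' Walks each read's op list from its mapped start and emits one signature
#' per insertion/deletion op of at least `min_sv_len` bases.  Soft-clip-only
#' evidence is handled separately (see [collect_clips()]).
#'
#' @param reads An `aligned_reads` data.frame.
#' @param min_sv_len Minimum op length to report.
#' @return data.frame with columns `read_id`, `kind` (`INS`/`DEL`),
#'   `ref_position` (for `INS` the last reference base before the insert; for
#'   `DEL` the first deleted base), `length`, `inserted_sequence`.
#' @export
collect_signatures <- function(reads, min_sv_len = 30L) {
  out <- list()
  for (i in seq_len(nrow(reads))) {
    ops <- cigar_ops(reads$cigar[i])
    if (query_width(ops) != nchar(reads$sequence[i]))
      stop("malformed op list for read ", reads$read_id[i],
           ": query length mismatch", call. = FALSE)
    ref <- reads$mapped_start[i]   # next reference base to consume
    qry <- 1L                      # next query base to consume
    for (j in seq_len(nrow(ops))) {
      k <- ops$kind[j]; l <- ops$len[j]
      if (k == "I" && l >= min_sv_len)
        out[[length(out) + 1L]] <- data.frame(
          read_id = reads$read_id[i], kind = "INS", ref_position = ref - 1L,
          length = l,
          inserted_sequence = substr(reads$sequence[i], qry, qry + l - 1L))
      if (k == "D" && l >= min_sv_len)
        out[[length(out) + 1L]] <- data.frame(
          read_id = reads$read_id[i], kind = "DEL", ref_position = ref,
          length = l, inserted_sequence = NA_character_)
      if (k %in% c("M", "D")) ref <- ref + l
      if (k %in% c("M", "I", "S")) qry <- qry + l
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(read_id = character(), kind = character(),
                  ref_position = integer(), length = integer(),
                  inserted_sequence = character())
}

## deterministic low median for integer vectors
imedian <- function(x) sort(x)[ceiling(length(x) / 2)]

#' Cluster SV signatures into calls
#'
#' Signatures of the same kind within `window` bp of each other (single
#' linkage on position) merge into one call with median breakpoint and
#' length; clusters supported by fewer than `min_support` reads are dropped.
#'
#' @param signatures Output of [collect_signatures()].
#' @param window Single-linkage merge distance in bp.
#' @param min_support Minimum supporting reads per call.
#' @return data.frame of class `sv_calls`: `kind`, `ref_start` (INS: last
#'   base before the insert; DEL: first deleted base), `ref_end` (DEL only),
#'   `length`, `support`, `ci` (max deviation of member positions from the
#'   median), `consensus_insert` (INS), `hgvs`.
#' @export
cluster_signatures <- function(signatures, window = 50L, min_support = 3L) {
  if (window < 0L) stop("window must be >= 0", call. = FALSE)
  out <- list()
  for (k in c("INS", "DEL")) {
    sig <- signatures[signatures$kind == k, , drop = FALSE]
    if (nrow(sig) == 0L) next
    sig <- sig[order(sig$ref_position, sig$read_id), , drop = FALSE]
    brk <- c(0L, which(diff(sig$ref_position) > window), nrow(sig))
    for (b in seq_len(length(brk) - 1L)) {
      cl <- sig[(brk[b] + 1L):brk[b + 1L], , drop = FALSE]
      if (nrow(cl) < min_support) next
      pos <- imedian(cl$ref_position)
      len <- imedian(cl$length)
      cons <- if (k == "INS") consensus_insert(cl$inserted_sequence) else NA_character_
      out[[length(out) + 1L]] <- data.frame(
        kind = k, ref_start = pos,
        ref_end = if (k == "DEL") pos + len - 1L else NA_integer_,
        length = len, support = nrow(cl),
        ci = max(abs(cl$ref_position - pos)),
        consensus_insert = cons,
        hgvs = if (k == "INS") hgvs_describe("insertion", pos, length = len)
               else hgvs_describe("deletion", pos, end = pos + len - 1L))
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(kind = character(), ref_start = integer(),
                         ref_end = integer(), length = integer(),
                         support = integer(), ci = integer(),
                         consensus_insert = character(), hgvs = character())
  class(res) <- c("sv_calls", "data.frame")
  res
}

#' Majority-polished consensus of inserted sequences
#'
#' Picks the medoid (minimum summed Levenshtein distance, ties by input
#' order), aligns every sequence to it globally, and emits the per-column
#' majority over the medoid's columns (ties resolved toward the medoid's own
#' base).
#'
#' @param sequences Character vector of inserted sequences (>= 1).
#' @return A single consensus sequence.
#' @export
consensus_insert <- function(sequences) {
  if (length(sequences) == 0L) stop("no sequences", call. = FALSE)
  if (length(unique(sequences)) == 1L) return(sequences[1L])
  d <- adist(sequences)
  medoid <- sequences[which.min(rowSums(d))]
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  counts <- matrix(0L, nrow = 5L, ncol = nchar(medoid),
                   dimnames = list(c(DNA_BASES, "-"), NULL))
  for (s in sequences) {
    aln <- Biostrings::pairwiseAlignment(s, medoid, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2)
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    q <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    col <- 0L
    for (i in seq_along(q)) {
      if (q[i] == "-") next         # insertion relative to the medoid: skip
      col <- col + 1L
      counts[p[i], col] <- counts[p[i], col] + 1L
    }
  }
  med <- strsplit(medoid, "")[[1]]
  out <- vapply(seq_len(ncol(counts)), function(j) {
    top <- max(counts[, j])
    cand <- rownames(counts)[counts[, j] == top]
    if (med[j] %in% cand) med[j] else cand[1L]
  }, character(1))
  paste(out[out != "-"], collapse = "")
}

#' Read a repeat-annotation BED file
#'
#' Standard 0-based half-open BED with the repeat given in the name column as
#' `family:class` (e.g. `L2:LINE`); converted to 1-based inclusive
#' coordinates at this boundary.
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive),
#'   `family`, `class`.
#' @export
read_repeat_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- if (!is.null(gr$name)) gr$name else rep("unknown:unknown", length(gr))
  parts <- strsplit(nm, ":", fixed = TRUE)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),   # rtracklayer already 1-based
             end = GenomicRanges::end(gr),
             family = vapply(parts, `[`, "", 1L),
             class = vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_,
                            NA_character_))
}

#' Repeat context of a breakpoint position
#'
#' @param position 1-based reference position.
#' @param repeats data.frame as from [read_repeat_bed()] (or built directly
#'   with 1-based inclusive `start`/`end`, `family`, `class`).
#' @return A list with `containing_repeat` (list `family`, `class`, or
#'   `NULL`), `nearest_upstream` and `nearest_downstream` (each a list
#'   `family`, `class`, `distance` in bp — the gap between the position and
#'   the interval edge — or `NULL`).
#' @export
annotate_repeat_context <- function(position, repeats) {
  position <- as.integer(position)
  if (nrow(repeats) == 0L)
    return(list(containing_repeat = NULL, nearest_upstream = NULL,
                nearest_downstream = NULL))
  inside <- repeats$start <= position & position <= repeats$end
  containing <- if (any(inside)) {
    i <- which(inside)[1L]
    list(family = repeats$family[i], class = repeats$class[i])
  } else NULL
  up <- repeats[repeats$end < position, , drop = FALSE]
  nearest_up <- if (nrow(up)) {
    i <- which.max(up$end)
    list(family = up$family[i], class = up$class[i],
         distance = position - up$end[i])
  } else NULL
  down <- repeats[repeats$start > position, , drop = FALSE]
  nearest_down <- if (nrow(down)) {
    i <- which.min(down$start)
    list(family = down$family[i], class = down$class[i],
         distance = down$start[i] - position)
  } else NULL
  list(containing_repeat = containing, nearest_upstream = nearest_up,
       nearest_downstream = nearest_down)
}
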