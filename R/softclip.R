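## Soft-clip evidence around a candidate insertion site: clip clustering,
## clipped-base consensus, clipped-read fraction and coverage drop.

## reference span covered by a read (M/D ops)
read_ref_span <- function(mapped_start, cigar) {
  w <- ref_width(cigar_ops(cigar))
  c(start = mapped_start, end = mapped_start + max(w - 1L, 0L))
}

#' Collect soft-clip clusters near a position
#'
#' Reads whose clip boundary (the reference coordinate where aligned bases
#' stop and clipped bases begin) lies within `window` of `locus_position`
#' are grouped by boundary position and side.  A trailing `S` op clips on
#' the `right` side (boundary = mapped start + reference span), a leading
#' `S` op on the `left` side (boundary = mapped start).  Fully soft-clipped
#' reads carry no alignment anchor and are skipped.
#'
#' @param reads An `aligned_reads` data.frame.
#' @param locus_position 1-based reference position of the candidate site.
#' @param window Maximum distance of the clip boundary from the site.
#' @param min_clip_len Minimum clipped bases for a read to count as clipped.
#' @return A list of clusters, each with `ref_position`, `side`,
#'   `clipped_sequences`, `n_clipped`, `n_total_overlapping` (reads whose
#'   aligned span covers `locus_position`).
#' @export
collect_clips <- function(reads, locus_position, window = 10L, min_clip_len = 8L) {
  if (window < 0L || min_clip_len < 1L)
    stop("window must be >= 0 and min_clip_len >= 1", call. = FALSE)
  n_total <- 0L
  clips <- list()
  for (i in seq_len(nrow(reads))) {
    ops <- cigar_ops(reads$cigar[i])
    if (query_width(ops) != nchar(reads$sequence[i]))
      stop("malformed op list for read ", reads$read_id[i], call. = FALSE)
    if (!any(ops$kind == "M")) next
    span <- read_ref_span(reads$mapped_start[i], reads$cigar[i])
    if (span["start"] <= locus_position && locus_position <= span["end"])
      n_total <- n_total + 1L
    first <- ops[1L, ]; last <- ops[nrow(ops), ]
    if (first$kind == "S" && first$len >= min_clip_len) {
      boundary <- reads$mapped_start[i]
      if (abs(boundary - locus_position) <= window)
        clips[[length(clips) + 1L]] <- data.frame(
          pos = boundary, side = "left",
          seq = substr(reads$sequence[i], 1L, first$len))
    }
    if (last$kind == "S" && last$len >= min_clip_len) {
      boundary <- unname(span["end"]) + 1L
      if (abs(boundary - locus_position) <= window)
        clips[[length(clips) + 1L]] <- data.frame(
          pos = boundary, side = "right",
          seq = substr(reads$sequence[i],
                       nchar(reads$sequence[i]) - last$len + 1L,
                       nchar(reads$sequence[i])))
    }
  }
  if (!length(clips)) return(list())
  df <- do.call(rbind, clips)
  out <- lapply(split(df, list(df$pos, df$side), drop = TRUE), function(g) {
    list(ref_position = g$pos[1L], side = g$side[1L],
         clipped_sequences = g$seq, n_clipped = nrow(g),
         n_total_overlapping = n_total)
  })
  unname(out[order(vapply(out, function(cl) cl$ref_position, 1))])
}

#' Percentage of clipped reads, rounded for reporting
#'
#' @param n_clipped,n_total Read counts.
#' @return `100 * n_clipped / n_total`, rounded to the nearest integer.
#' @export
clip_percent <- function(n_clipped, n_total) {
  if (n_total <= 0) stop("n_total must be > 0", call. = FALSE)
  round(100 * n_clipped / n_total)
}

## per-column majority consensus of clip sequences anchored at the boundary:
## right-side clips share their first column, left-side clips their last
clip_consensus <- function(sequences, side) {
  if (side == "left") sequences <- vapply(sequences, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), "", USE.NAMES = FALSE)
  width <- max(nchar(sequences))
  cons <- vapply(seq_len(width), function(j) {
    col <- substr(sequences, j, j)
    col <- col[col != ""]
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[1L]
  }, character(1))
  cons <- paste(cons, collapse = "")
  if (side == "left") paste(rev(strsplit(cons, "")[[1]]), collapse = "") else cons
}

#' Summarize a soft-clip cluster
#'
#' @param cluster One cluster from [collect_clips()].
#' @param expected The insert sequence expected at this side of the junction
#'   (prefix of the insert for a right-side cluster, suffix for a left-side
#'   cluster); compared with the clip consensus over the shorter of the two
#'   at a 90% identity threshold.
#' @param coverage_in_window,coverage_flanking Mean read depth at the
#'   junction and in flanking windows (see [junction_coverage()]).
#' @return A list of class `clip_summary`: `percent_clipped`,
#'   `consensus_sequence`, `matches_expected`, `coverage_drop`
#'   (`1 - in/flank`, floored at 0).
#' @export
clip_summary <- function(cluster, expected = NULL,
                         coverage_in_window = NA_real_,
                         coverage_flanking = NA_real_) {
  if (is.null(cluster) || cluster$n_clipped == 0L)
    stop("empty cluster", call. = FALSE)
  cons <- clip_consensus(cluster$clipped_sequences, cluster$side)
  matches <- NA
  if (!is.null(expected)) {
    n <- min(nchar(cons), nchar(expected))
    a <- if (cluster$side == "right") substr(cons, 1L, n)
         else substr(cons, nchar(cons) - n + 1L, nchar(cons))
    b <- if (cluster$side == "right") substr(expected, 1L, n)
         else substr(expected, nchar(expected) - n + 1L, nchar(expected))
    ident <- mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
    matches <- ident >= 0.9
  }
  drop <- if (is.na(coverage_in_window) || is.na(coverage_flanking) ||
              coverage_flanking == 0) NA_real_
          else max(0, 1 - coverage_in_window / coverage_flanking)
  structure(list(percent_clipped = clip_percent(cluster$n_clipped,
                                                cluster$n_total_overlapping),
                 consensus_sequence = cons,
                 matches_expected = matches,
                 coverage_drop = drop),
            class = "clip_summary")
}

#' Mean aligned depth at a junction and in flanking windows
#'
#' In-window depth is the mean aligned (M-op) coverage over `position` +/-
#' 25 bp; flanking depth is the mean over two 100-bp windows whose inner
#' edges lie 200 bp from the position.
#'
#' @param reads An `aligned_reads` data.frame.
#' @param position 1-based reference position of the junction.
#' @return A list with `in_window` and `flanking`.
#' @export
junction_coverage <- function(reads, position) {
  depth_over <- function(lo, hi) {
    cov <- integer(hi - lo + 1L)
    for (i in seq_len(nrow(reads))) {
      ops <- cigar_ops(reads$cigar[i])
      ref <- reads$mapped_start[i]
      for (j in seq_len(nrow(ops))) {
        if (ops$kind[j] == "M") {
          a <- max(ref, lo); b <- min(ref + ops$len[j] - 1L, hi)
          if (a <= b) cov[(a - lo + 1L):(b - lo + 1L)] <-
              cov[(a - lo + 1L):(b - lo + 1L)] + 1L
        }
        if (ops$kind[j] %in% c("M", "D")) ref <- ref + ops$len[j]
      }
    }
    mean(cov)
  }
  list(in_window = depth_over(position - 25L, position + 25L),
       flanking = mean(c(depth_over(position - 300L, position - 201L),
                         depth_over(position + 201L, position + 300L))))
}
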