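## Streaming probe-count screening of short-read data: per-read WT/MUT
## junction matching, VAF computation, genotype calling and cohort reports.

#' Default genotype-calling thresholds
#'
#' `min_total` informative reads for any call, `min_mut_reads` supporting
#' reads and `het_vaf_min` VAF for a heterozygous call, `hom_vaf_min` VAF
#' for a homozygous call.  Conventional diagnostic defaults; fully
#' configurable.
#'
#' @return Named list of thresholds.
#' @export
screen_thresholds <- function() {
  list(min_total = 10L, min_mut_reads = 3L, het_vaf_min = 0.2, hom_vaf_min = 0.8)
}

#' Count probe-matching reads in a FASTQ/SAM stream
#'
#' A read increments the MUT count when its sequence contains any validated
#' MUT probe as an exact substring (case-insensitive), the WT count when it
#' contains any WT probe; a read matching both classes increments only a
#' conflict counter.  Probes already encode both strands, so reads are not
#' reverse-complemented.  Matching-read counting is equivalent to `grep -c`
#' line counting on FASTQ sequence lines.
#'
#' @param x Path to a FASTQ file (optionally `.gz`), path to a SAM-dialect
#'   file, or a character vector of read sequences.
#' @param probes A validated `probe_set` containing both allele classes.
#' @param format `"auto"` (by extension), `"fastq"`, `"sam"` or
#'   `"sequences"`.
#' @return A list with `mut_reads`, `wt_reads`, `conflict_reads`, `total`.
#' @export
scan_stream <- function(x, probes, format = c("auto", "fastq", "sam", "sequences")) {
  format <- match.arg(format)
  ok <- probes[!is.na(probes$validated) & probes$validated, , drop = FALSE]
  if (!all(c("MUT", "WT") %in% ok$allele_class))
    stop("probe set must contain validated probes of both classes", call. = FALSE)
  if (format == "auto")
    format <- if (length(x) == 1L && grepl("\\.sam$", x)) "sam"
              else if (length(x) == 1L && grepl("\\.(fastq|fq)(\\.gz)?$", x)) "fastq"
              else "sequences"
  seqs <- switch(format,
                 fastq = read_fastq_sequences(x),
                 sam = read_sam(x)$sequence,
                 sequences = x)
  seqs <- toupper(seqs)
  match_any <- function(class) {
    pr <- ok$sequence[ok$allele_class == class]
    hit <- rep(FALSE, length(seqs))
    for (p in pr) hit <- hit | grepl(p, seqs, fixed = TRUE)
    hit
  }
  m <- match_any("MUT"); w <- match_any("WT")
  list(mut_reads = sum(m & !w), wt_reads = sum(w & !m),
       conflict_reads = sum(m & w), total = length(seqs))
}

#' Call a genotype from probe counts
#'
#' VAF is mutant reads over total informative reads
#' (`mut / (mut + wt)`).  `no_call` below `min_total` informative reads;
#' `mut/mut` at VAF >= `hom_vaf_min`; `ref/mut` at VAF >= `het_vaf_min` with
#' at least `min_mut_reads` supporting reads; otherwise `ref/ref`.
#'
#' @param mut_reads,wt_reads Non-negative read counts.
#' @param thresholds See [screen_thresholds()].
#' @return A list with `genotype` and `vaf` (`NA` when uncallable).
#' @export
call_genotype <- function(mut_reads, wt_reads, thresholds = screen_thresholds()) {
  if (is.na(mut_reads) || is.na(wt_reads) || mut_reads < 0 || wt_reads < 0)
    stop("counts must be non-negative", call. = FALSE)
  th <- thresholds
  total <- mut_reads + wt_reads
  if (total < th$min_total) return(list(genotype = "no_call", vaf = NA_real_))
  vaf <- mut_reads / total
  genotype <- if (vaf >= th$hom_vaf_min) "mut/mut"
              else if (vaf >= th$het_vaf_min && mut_reads >= th$min_mut_reads) "ref/mut"
              else "ref/ref"
  list(genotype = genotype, vaf = vaf)
}

#' Screen a cohort of sample files
#'
#' Applies [scan_stream()] and [call_genotype()] to each sample; per-sample
#' I/O errors are reported in that sample's row (`no_call`, `note` column)
#' without aborting the cohort.
#'
#' @param files Character vector of per-sample FASTQ/SAM paths; names (or
#'   file base names) become sample ids.
#' @param probes A validated `probe_set`.
#' @param thresholds See [screen_thresholds()].
#' @return A data.frame of class `cohort_report` with columns `sample_id`,
#'   `mut_reads`, `wt_reads`, `vaf`, `genotype`, `total_reads_scanned`,
#'   `note`; attributes `n_carriers` and `n_samples`.
#' @export
screen_cohort <- function(files, probes, thresholds = screen_thresholds()) {
  if (length(files) < 1L) stop("need >= 1 sample", call. = FALSE)
  ids <- names(files)
  if (is.null(ids)) ids <- sub("\\.(fastq|fq|sam)(\\.gz)?$", "", basename(files))
  rows <- lapply(seq_along(files), function(i) {
    res <- tryCatch({
      cnt <- scan_stream(files[i], probes)
      gt <- call_genotype(cnt$mut_reads, cnt$wt_reads, thresholds)
      data.frame(sample_id = ids[i], mut_reads = cnt$mut_reads,
                 wt_reads = cnt$wt_reads, vaf = gt$vaf, genotype = gt$genotype,
                 total_reads_scanned = cnt$total, note = "")
    }, error = function(e)
      data.frame(sample_id = ids[i], mut_reads = NA_integer_,
                 wt_reads = NA_integer_, vaf = NA_real_, genotype = "no_call",
                 total_reads_scanned = NA_integer_, note = conditionMessage(e)))
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            n_carriers = sum(out$genotype %in% c("ref/mut", "mut/mut")),
            n_samples = nrow(out),
            class = c("cohort_report", "data.frame"))
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort screen: %d samples, %d carrier(s)\n",
              attr(x, "n_samples"), attr(x, "n_carriers")))
  NextMethod()
}
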