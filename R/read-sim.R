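## Read simulation against an allele pair, with truthful alignment ops
## computed relative to the wild-type reference, plus minimal FASTQ and
## SAM-dialect text IO.

## ops (as a kind/len data.frame) for a mutant-haplotype read s..e (mutant
## local coords) against the WT reference; returns NULL for reads entirely
## inside an insertion (unalignable without the element)
mut_read_ops <- function(pair, s, e) {
  if (pair$kind == "insertion") {
    ia <- pair$insert_after_local
    L <- nchar(pair$insert_seq)
    if (e <= ia) return(list(start = s, kind = "M", len = e - s + 1L))
    if (s > ia + L) return(list(start = s - L, kind = "M", len = e - s + 1L))
    if (s <= ia && e > ia + L)
      return(list(start = s, kind = c("M", "I", "M"),
                  len = c(ia - s + 1L, L, e - ia - L)))
    if (s <= ia)                                   # runs into the insert
      return(list(start = s, kind = c("M", "S"),
                  len = c(ia - s + 1L, e - ia)))
    if (e > ia + L)                                # starts inside the insert
      return(list(start = ia + 1L, kind = c("S", "M"),
                  len = c(ia + L - s + 1L, e - ia - L)))
    NULL                                           # fully inside the insert
  } else {
    ds <- pair$del_start_local
    D <- pair$del_end_local - ds + 1L
    if (e < ds) return(list(start = s, kind = "M", len = e - s + 1L))
    if (s >= ds) return(list(start = s + D, kind = "M", len = e - s + 1L))
    list(start = s, kind = c("M", "D", "M"),
         len = c(ds - s, D, e - ds + 1L))
  }
}

inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    v <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(v)) < error_rate)
    for (i in hit) v[i] <- sample(setdiff(DNA_BASES, v[i]), 1L)
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate reads from an allele pair
#'
#' Reads are drawn uniformly from the two haplotypes according to the
#' genotype, substitution errors are injected at `error_rate`, and alignment
#' ops against the wild-type reference are computed from the construction
#' (mutant reads spanning an insertion carry an `I` op, reads partially
#' overlapping an insertion junction carry an `S` soft-clip, deletion
#' spanners carry a `D` op).  Reads falling entirely inside an insertion are
#' unalignable against the reference and are reported with a fully
#' soft-clipped op list anchored at the insertion point.
#'
#' @param pair An [build_alleles()] result.
#' @param genotype `"ref/ref"`, `"ref/mut"` or `"mut/mut"`.
#' @param depth Target mean coverage (split evenly across haplotypes for
#'   heterozygotes).
#' @param read_len Read length (must not exceed the haplotype length).
#' @param error_rate Per-base substitution error probability (`0 <= e < 0.5`).
#' @param mode `"short"` or `"long"`; metadata only, geometry is driven by
#'   `read_len`.
#' @param seed Integer seed.
#' @param sample_id Sample label stored with each read.
#' @return A data.frame of class `aligned_reads` with columns `read_id`,
#'   `sample_id`, `haplotype`, `mapped_start` (1-based reference coordinate),
#'   `cigar` and `sequence`.
#' @export
simulate_reads <- function(pair, genotype = c("ref/ref", "ref/mut", "mut/mut"),
                           depth = 30, read_len = 100L, error_rate = 0,
                           mode = c("short", "long"), seed = 1L,
                           sample_id = "S1") {
  genotype <- match.arg(genotype); mode <- match.arg(mode)
  stopifnot(inherits(pair, "allele_pair"))
  read_len <- as.integer(read_len)
  if (read_len < 1L) stop("read_len must be >= 1", call. = FALSE)
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must be in [0, 0.5)", call. = FALSE)
  haps <- switch(genotype,
                 "ref/ref" = c(wt = 1, mut = 0),
                 "ref/mut" = c(wt = 0.5, mut = 0.5),
                 "mut/mut" = c(wt = 0, mut = 1))
  out <- list()
  withr::with_seed(seed, {
    for (h in names(haps)[haps > 0]) {
      hseq <- pair[[h]]
      hlen <- nchar(hseq)
      if (read_len > hlen)
        stop("read_len exceeds ", h, " haplotype length", call. = FALSE)
      n <- ceiling(depth * haps[[h]] * hlen / read_len)
      starts <- sample.int(hlen - read_len + 1L, n, replace = TRUE)
      seqs <- substring(hseq, starts, starts + read_len - 1L)
      seqs <- inject_errors(seqs, error_rate)
      if (h == "wt") {
        rows <- data.frame(haplotype = "wt",
                           mapped_start = local_to_ref(pair$locus, starts),
                           cigar = paste0(read_len, "M"), sequence = seqs)
      } else {
        rows <- do.call(rbind, lapply(seq_len(n), function(i) {
          op <- mut_read_ops(pair, starts[i], starts[i] + read_len - 1L)
          if (is.null(op)) {
            anchor <- if (pair$kind == "insertion") pair$insert_after_local
                      else pair$del_start_local
            op <- list(start = anchor, kind = "S", len = read_len)
          }
          data.frame(haplotype = "mut",
                     mapped_start = local_to_ref(pair$locus, op$start),
                     cigar = ops_to_cigar(op$kind, op$len), sequence = seqs[i])
        }))
      }
      out[[h]] <- rows
    }
  })
  res <- do.call(rbind, out)
  res <- data.frame(read_id = sprintf("%s_r%04d", sample_id, seq_len(nrow(res))),
                    sample_id = sample_id, res, row.names = NULL)
  class(res) <- c("aligned_reads", "data.frame")
  res
}

## ---- text IO ---------------------------------------------------------------

#' Write reads as FASTQ
#'
#' Four-line records with constant dummy qualities (`I`); `.gz` paths are
#' compressed transparently.
#'
#' @param reads An `aligned_reads` data.frame (or any data.frame with
#'   `read_id` and `sequence`).
#' @param path Output path; compressed when it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  qual <- strrep("I", nchar(reads$sequence))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", qual), con)
  invisible(path)
}

#' Read the sequences of a FASTQ file
#'
#' @param path FASTQ path (optionally gzip-compressed).
#' @return Character vector of read sequences.
#' @export
read_fastq_sequences <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ (records are not 4-line blocks): ", path, call. = FALSE)
  if (length(lines) == 0L) return(character(0))
  lines[seq(2L, length(lines), by = 4L)]
}

#' Write reads as SAM-dialect text
#'
#' Emits the eleven mandatory SAM columns (QNAME, FLAG, RNAME, POS, MAPQ,
#' CIGAR, RNEXT, PNEXT, TLEN, SEQ, QUAL) without a header — enough for
#' re-import by [read_sam()] and for line-grep screening.
#'
#' @param reads An `aligned_reads` data.frame.
#' @param path Output path.
#' @param rname Reference name to place in RNAME.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, rname = "chr6") {
  df <- data.frame(reads$read_id, 0L, rname, reads$mapped_start, 60L,
                   reads$cigar, "*", 0L, 0L, reads$sequence, "*")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read SAM-dialect text back into an `aligned_reads` frame
#'
#' @param path Path written by [write_sam()] (header lines starting with `@`
#'   are skipped).
#' @return An `aligned_reads` data.frame.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    res <- data.frame(read_id = character(), sample_id = character(),
                      haplotype = character(), mapped_start = integer(),
                      cigar = character(), sequence = character())
  } else {
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(f) < 10L)) stop("malformed SAM-dialect line", call. = FALSE)
    res <- data.frame(read_id = vapply(f, `[`, "", 1L),
                      sample_id = NA_character_,
                      haplotype = NA_character_,
                      mapped_start = as.integer(vapply(f, `[`, "", 4L)),
                      cigar = vapply(f, `[`, "", 6L),
                      sequence = vapply(f, `[`, "", 10L))
  }
  class(res) <- c("aligned_reads", "data.frame")
  res
}

#' Simulate a short-read cohort
#'
#' Writes one FASTQ(.gz) per sample plus a genotype truth table.
#'
#' @param genotypes Character vector of per-sample genotypes
#'   (`"ref/ref"`, `"ref/mut"`, `"mut/mut"`); names, if set, become sample
#'   ids.
#' @param pair An [build_alleles()] result.
#' @param dir Output directory (created if needed).
#' @param depth,read_len,error_rate Per-sample simulation settings.
#' @param seed Integer seed; per-sample seeds are derived from it.
#' @param gzip Compress the per-sample FASTQ files.
#' @return The truth table: data.frame with `sample_id`, `genotype`, `file`.
#'   Also written to `dir/truth.tsv`.
#' @export
simulate_cohort <- function(genotypes, pair, dir, depth = 5, read_len = 100L,
                            error_rate = 0, seed = 1L, gzip = TRUE) {
  stopifnot(length(genotypes) >= 1L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- names(genotypes)
  if (is.null(ids)) ids <- sprintf("sample%03d", seq_along(genotypes))
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  files <- file.path(dir, paste0(ids, ext))
  for (i in seq_along(genotypes)) {
    reads <- simulate_reads(pair, genotypes[[i]], depth = depth,
                            read_len = read_len, error_rate = error_rate,
                            seed = (seed + i) %% .Machine$integer.max,
                            sample_id = ids[i])
    write_fastq(reads, files[i])
  }
  truth <- data.frame(sample_id = ids, genotype = unname(genotypes), file = files)
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth
}
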