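## End-to-end orchestration: long-read characterization and short-read
## cohort screening, with machine-readable run manifests.

write_manifest <- function(out_dir, stage, inputs, params, seed = NA) {
  if (is.null(out_dir)) return(invisible(NULL))
  manifest <- list(
    stage = stage, inputs = inputs, params = params, seed = seed,
    package = "meiscreen",
    version = as.character(utils::packageVersion("meiscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Characterize structural variants from aligned long reads
#'
#' Chains signature collection, clustering, insert consensus, insertion
#' decomposition and repeat-context annotation.  Insertion calls are
#' decomposed against the consensus library using flanks taken from the
#' locus reference; deletion-call breakpoints are annotated against the
#' repeat track when one is supplied.
#'
#' @param reads An `aligned_reads` data.frame (e.g. from [simulate_reads()]
#'   or [read_sam()]).
#' @param locus The reference [locus_config()] the reads are aligned to.
#' @param library Consensus element library data.frame.
#' @param repeats Optional repeat annotation data.frame
#'   (see [read_repeat_bed()]).
#' @param params Optional list: `min_sv_len`, `window`, `min_support`, plus
#'   decomposition parameters passed through to [decompose_insertion()].
#' @param out_dir Optional directory for TSV outputs and a JSON run manifest.
#' @return A list with `calls` (an `sv_calls` data.frame), `mei_reports`
#'   (one `mei_report` per INS call), `repeat_context` (one per DEL call
#'   breakpoint pair, or `NULL`).
#' @export
run_characterize <- function(reads, locus, library = default_consensus_library(),
                             repeats = NULL, params = list(), out_dir = NULL) {
  p <- modifyList(list(min_sv_len = 30L, window = 50L, min_support = 3L), params)
  if (nrow(reads) == 0L) {
    warning("no input reads; empty call set")
    return(list(calls = cluster_signatures(collect_signatures(reads)),
                mei_reports = list(), repeat_context = NULL))
  }
  sig <- collect_signatures(reads, min_sv_len = p$min_sv_len)
  calls <- cluster_signatures(sig, window = p$window, min_support = p$min_support)
  mei <- list()
  for (i in which(calls$kind == "INS")) {
    ia <- ref_to_local(locus, calls$ref_start[i])
    call <- insertion_call(
      ref_position = calls$ref_start[i],
      insert_sequence = calls$consensus_insert[i],
      left_flank = substr1(locus$wt_sequence, max(1L, ia - 100L + 1L), ia),
      right_flank = substr1(locus$wt_sequence, ia + 1L,
                            min(nchar(locus$wt_sequence), ia + 100L)))
    mei[[length(mei) + 1L]] <- decompose_insertion(call, library, params = p)
  }
  ctx <- NULL
  if (!is.null(repeats) && any(calls$kind == "DEL")) {
    ctx <- lapply(which(calls$kind == "DEL"), function(i)
      list(five_prime = annotate_repeat_context(calls$ref_start[i], repeats),
           three_prime = annotate_repeat_context(calls$ref_end[i], repeats)))
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.table(calls, file.path(out_dir, "sv_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (length(mei))
      jsonlite::write_json(mei, file.path(out_dir, "mei_reports.json"),
                           auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    write_manifest(out_dir, "characterize",
                   inputs = list(n_reads = nrow(reads), locus = locus$ref_name),
                   params = p)
  }
  list(calls = calls, mei_reports = mei, repeat_context = ctx)
}

#' Screen a short-read cohort for a characterized insertion
#'
#' Designs junction probes from the allele pair (unless a probe set is
#' supplied), validates them against the alleles and background, aborts if
#' any designed probe fails validation, and screens every sample file.
#'
#' @param pair An insertion [build_alleles()] result.
#' @param files Per-sample FASTQ/SAM paths.
#' @param probes Optional `probe_set` to use instead of a fresh design.
#' @param background Background sequences for specificity checking.
#' @param thresholds Genotype thresholds, see [screen_thresholds()].
#' @param k,sides Passed to [design_junction_probes()].
#' @param out_dir Optional directory for the report TSV and run manifest.
#' @return A `cohort_report` data.frame (see [screen_cohort()]).
#' @export
run_screen <- function(pair, files, probes = NULL, background = character(),
                       thresholds = screen_thresholds(), k = 23L,
                       sides = list(), out_dir = NULL) {
  if (is.null(probes))
    probes <- design_junction_probes(pair, k = k, sides = sides)
  probes <- check_specificity(probes, mut_allele = pair$mut,
                              wt_allele = pair$wt, background = background)
  if (!all(probes$validated))
    stop("unvalidated probes; refusing to screen: ",
         paste(probes$sequence[!probes$validated], collapse = ", "),
         call. = FALSE)
  report <- screen_cohort(files, probes, thresholds)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.table(as.data.frame(report), file.path(out_dir, "screen_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(probes), file.path(out_dir, "probes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(out_dir, "screen",
                   inputs = list(n_samples = length(files)),
                   params = list(k = k, thresholds = thresholds))
  }
  report
}
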