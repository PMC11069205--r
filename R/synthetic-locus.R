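## Locus configuration, variant specs, and allele construction.
##
## Coordinates follow the HGVS convention: all user-facing positions are
## 1-based inclusive reference coordinates.  Internally, positions local to a
## locus are 1-based offsets into its wild-type sequence; the conversion layer
## is local_to_ref()/ref_to_local().

#' Define a local reference locus
#'
#' A locus is a named stretch of reference sequence together with the 1-based
#' reference coordinate of its first base, so that kilobase-scale alleles can
#' be simulated while reporting genome-style coordinates.
#'
#' @param ref_name Reference/chromosome label.
#' @param ref_offset 1-based reference coordinate of the first base of
#'   `wt_sequence`.
#' @param wt_sequence Wild-type haplotype sequence (strict ACGT).
#' @return An object of class `locus_config`.
#' @export
locus_config <- function(ref_name, ref_offset, wt_sequence) {
  assert_dna(wt_sequence, "wt_sequence")
  if (!nzchar(wt_sequence)) stop("wt_sequence must be non-empty", call. = FALSE)
  ref_offset <- as.integer(ref_offset)
  if (is.na(ref_offset) || ref_offset < 1L)
    stop("ref_offset must be >= 1", call. = FALSE)
  structure(list(ref_name = ref_name, ref_offset = ref_offset,
                 wt_sequence = wt_sequence),
            class = "locus_config")
}

#' Convert between local and reference coordinates
#'
#' @param locus A [locus_config()].
#' @param pos Position(s) to convert (1-based).
#' @return Converted integer position(s).
#' @export
local_to_ref <- function(locus, pos) as.integer(pos) + locus$ref_offset - 1L

#' @rdname local_to_ref
#' @export
ref_to_local <- function(locus, pos) {
  out <- as.integer(pos) - locus$ref_offset + 1L
  if (any(out < 1L | out > nchar(locus$wt_sequence)))
    stop("reference position outside locus", call. = FALSE)
  out
}

#' Specify a mobile-element style insertion
#'
#' The insertion anatomy follows target-primed reverse transcription: the
#' reference ends with the target-site duplication (TSD) immediately 5' of the
#' insertion point, and the inserted sequence carries the element body, the
#' homopolymer tail and a second copy of the TSD.  On the construction (plus)
#' strand the layouts are `body + tail + TSD` for a plus-orientation element
#' and `tail + revcomp(body) + TSD` for a minus-orientation element.
#'
#' @param insert_after 1-based reference coordinate of the last base before
#'   the insertion.
#' @param tsd TSD sequence as it appears on the plus strand (must equal the
#'   reference bases immediately 5' of the insertion point).
#' @param body Element body sequence in element (plus) orientation.
#' @param tail_base Homopolymer base as it appears in the inserted sequence
#'   (`"A"` for plus-orientation elements, `"T"` for minus).
#' @param tail_len Tail length in bp (>= 0).
#' @param body_orientation `"plus"` or `"minus"`.
#' @return An object of class `insertion_spec`.
#' @export
insertion_spec <- function(insert_after, tsd, body, tail_base = "A",
                           tail_len = 0L, body_orientation = c("plus", "minus")) {
  body_orientation <- match.arg(body_orientation)
  assert_dna(tsd, "tsd"); assert_dna(body, "body")
  tail_base <- match.arg(tail_base, c("A", "T"))
  tail_len <- as.integer(tail_len)
  if (is.na(tail_len) || tail_len < 0L) stop("tail_len must be >= 0", call. = FALSE)
  structure(list(insert_after = as.integer(insert_after), tsd = tsd, body = body,
                 tail_base = tail_base, tail_len = tail_len,
                 body_orientation = body_orientation),
            class = "insertion_spec")
}

#' Specify a deletion
#'
#' @param del_start,del_end 1-based inclusive reference coordinates of the
#'   deleted segment.
#' @return An object of class `deletion_spec`.
#' @export
deletion_spec <- function(del_start, del_end) {
  del_start <- as.integer(del_start); del_end <- as.integer(del_end)
  if (del_start > del_end) stop("del_start must be <= del_end", call. = FALSE)
  structure(list(del_start = del_start, del_end = del_end),
            class = "deletion_spec")
}

## the full inserted string on the plus strand of construction
inserted_sequence <- function(spec) {
  tail <- strrep(spec$tail_base, spec$tail_len)
  if (spec$body_orientation == "plus")
    paste0(spec$body, tail, spec$tsd)
  else
    paste0(tail, revcomp(spec$body), spec$tsd)
}

#' Build the wild-type / mutant haplotype pair for a variant
#'
#' @param locus A [locus_config()].
#' @param variant An [insertion_spec()] or [deletion_spec()].
#' @return An object of class `allele_pair`: list with `wt`, `mut`, `locus`,
#'   `variant`, `kind`, and the local variant coordinates.
#' @export
build_alleles <- function(locus, variant) {
  wt <- locus$wt_sequence
  if (inherits(variant, "insertion_spec")) {
    ia <- ref_to_local(locus, variant$insert_after)
    tsd_len <- nchar(variant$tsd)
    if (tsd_len > 0L) {
      flank <- substr1(wt, ia - tsd_len + 1L, ia)
      if (!identical(flank, variant$tsd))
        stop("TSD does not match the reference bases 5' of the insertion point",
             call. = FALSE)
    }
    ins <- inserted_sequence(variant)
    mut <- paste0(substr1(wt, 1L, ia), ins, substr1(wt, ia + 1L, nchar(wt)))
    structure(list(wt = wt, mut = mut, locus = locus, variant = variant,
                   kind = "insertion", insert_after_local = ia,
                   insert_seq = ins),
              class = "allele_pair")
  } else if (inherits(variant, "deletion_spec")) {
    ds <- ref_to_local(locus, variant$del_start)
    de <- ref_to_local(locus, variant$del_end)
    mut <- paste0(substr1(wt, 1L, ds - 1L), substr1(wt, de + 1L, nchar(wt)))
    structure(list(wt = wt, mut = mut, locus = locus, variant = variant,
                   kind = "deletion", del_start_local = ds, del_end_local = de),
              class = "allele_pair")
  } else stop("variant must be an insertion_spec or deletion_spec", call. = FALSE)
}

## ---- the published EYS case, rebuilt from its printed sequences ------------

EYS_TSD_PLUS <- "GAAGGATACAATGTT"    # plus strand; minus strand AACATTGTATCCTTC
EYS_INS_AFTER <- 64430524L           # chr6 (GRCh37), last base before insert
EYS_DEL_START <- 64764235L
EYS_DEL_END <- 64820592L
EYS_TAIL_LEN <- 56L

## the six published junction/site probes (plus their layout in the alleles)
EYS_PROBES_WT <- c("ATTAGAAGGATACAATGTTTATG", "CATAAACATTGTATCCTTCTAAT")
EYS_PROBES_MUT <- c("GAAGGATACAATGTTGGCCGGGC", "GCCCGGCCAACATTGTATCCTTC",
                    "ACATTGTATCCTTCTTTTTTTT", "AAAAAAAAGAAGGATACAATGT")

## random flank that contains none of the published probes on either strand
probe_free_flank <- function(n) {
  avoid <- c(EYS_PROBES_WT, EYS_PROBES_MUT, revcomp(c(EYS_PROBES_WT, EYS_PROBES_MUT)))
  for (i in 1:20) {
    fl <- random_dna(n)
    if (!any(vapply(avoid, grepl, TRUE, x = fl, fixed = TRUE))) return(fl)
  }
  stop("could not generate a probe-free flank")  # nocov
}

#' The EYS AluYa5 / exon 32-33 deletion fixture
#'
#' Reconstructs, on the genomic plus strand, the two EYS structural variants
#' this package was built around: a heterozygous AluYa5 insertion in coding
#' exon 43 (body 282 bp, poly-A tail 56 bp on the plus strand, 15-bp TSD
#' `GAAGGATACAATGTT`, i.e. `AACATTGTATCCTTC` on the transcript strand) after
#' chr6:64,430,524 (GRCh37), and the recurrent ~56.4-kb deletion of exons
#' 32-33 at chr6:64,764,235-64,820,592.  The printed junction context
#' (`ATTA ... TATG`) and the TSD are exact; sequence beyond the printed bases
#' is seeded-random and guaranteed free of the published probe sequences.
#' The element body is the bundled 282-bp synthetic AluYa5-like consensus.
#'
#' @param seed Integer seed for the random flanks (the variant anatomy itself
#'   is fixed).
#' @param flank Flank length in bp on each side of the printed context.
#' @return A list with elements `insertion_locus` ([locus_config()]),
#'   `insertion` ([insertion_spec()]), `deletion_locus`, and `deletion`
#'   ([deletion_spec()]).
#' @export
eys_alu_fixture <- function(seed = 101L, flank = 1000L) {
  lib <- default_consensus_library()
  body <- lib$sequence[lib$family == "AluYa5"]
  if (length(body) != 1L) stop("bundled consensus library is missing its AluYa5 entry")
  withr::with_seed(seed, {
    left <- probe_free_flank(flank)
    right <- probe_free_flank(flank)
    del_wt <- random_dna(EYS_DEL_END - EYS_DEL_START + 1L + 2L * flank)
  })
  wt_ins <- paste0(left, "ATTA", EYS_TSD_PLUS, "TATG", right)
  ins_locus <- locus_config(
    ref_name = "chr6",
    ref_offset = EYS_INS_AFTER - (flank + 4L + nchar(EYS_TSD_PLUS)) + 1L,
    wt_sequence = wt_ins)
  ins <- insertion_spec(EYS_INS_AFTER, tsd = EYS_TSD_PLUS, body = body,
                        tail_base = "A", tail_len = EYS_TAIL_LEN,
                        body_orientation = "plus")
  del_locus <- locus_config("chr6", EYS_DEL_START - flank, del_wt)
  del <- deletion_spec(EYS_DEL_START, EYS_DEL_END)
  list(insertion_locus = ins_locus, insertion = ins,
       deletion_locus = del_locus, deletion = del)
}

#' Draw a random, decomposition-canonical insertion spec
#'
#' Generates a random locus plus insertion spec for round-trip testing of the
#' decomposition machinery.  Specs are emitted in canonical form, i.e. with
#' the TSD/tail/body partition identifiable: the body's tail-adjacent terminus
#' carries a 12-base window free of the tail base, the TSD does not begin with
#' the tail-adjacent insert base, and the reference base 5' of the TSD differs
#' from the insert base adjacent to the TSD copy (bases violating these rules
#' would belong to the tail or TSD under any consistent annotation, making the
#' planted lengths unobservable).
#'
#' @param seed Integer seed.
#' @param library Consensus library data.frame (see
#'   [default_consensus_library()]); bodies are drawn as prefixes of its
#'   entries.
#' @param flank Reference flank length on each side of the insertion point.
#' @return A list with `locus`, `spec` and `pair` (the built [build_alleles()]
#'   result).
#' @export
random_insertion_spec <- function(seed, library = default_consensus_library(),
                                  flank = 400L) {
  withr::with_seed(seed, {
    orientation <- sample(c("plus", "minus"), 1L)
    tail_base <- if (orientation == "plus") "A" else "T"
    tail_len <- sample(20:80, 1L)
    tsd_len <- sample(5:20, 1L)
    entry <- sample(nrow(library), 1L)
    cons <- library$sequence[entry]
    body_len <- sample(60:nchar(cons), 1L)
    body <- substr(cons, 1L, body_len)
    ## canonical form: tail-adjacent body terminus free of the tail base
    buf <- strsplit(substr(body, body_len - 11L, body_len), "")[[1]]
    hp <- if (orientation == "plus") "A" else "T"  # base the tail contributes
    ## plus layout: tail abuts the body 3' end; minus layout: tail abuts
    ## revcomp(body)'s 5' end, whose bases are complements of the body 3' end
    bad <- if (orientation == "plus") "A" else "A"  # complement of T is A
    buf[buf == bad] <- sample(setdiff(DNA_BASES, bad), sum(buf == bad), replace = TRUE)
    body <- paste0(substr(body, 1L, body_len - 12L), paste(buf, collapse = ""))

    wt <- random_dna(2L * flank)
    ia <- flank
    tsd <- substr(wt, ia - tsd_len + 1L, ia)
    ## adjacent-to-TSD insert base (last insert base before the TSD copy)
    adj <- if (orientation == "plus") hp else substr(revcomp(body), nchar(body), nchar(body))
    fix_base <- function(s, pos, not) {
      if (substr(s, pos, pos) %in% not) {
        repl <- sample(setdiff(DNA_BASES, not), 1L)
        substr(s, pos, pos) <- repl
      }
      s
    }
    ## the TSD must not begin with the insert base adjacent to its copy
    ## (tail base in the plus layout, body-derived base in the minus layout):
    ## such a boundary base could belong to either side
    wt <- fix_base(wt, ia - tsd_len + 1L, adj)
    ## reference base 5' of the TSD must differ from the adjacent insert base
    wt <- fix_base(wt, ia - tsd_len, adj)
    tsd <- substr(wt, ia - tsd_len + 1L, ia)
    locus <- locus_config("sim", 1L, wt)
    spec <- insertion_spec(ia, tsd = tsd, body = body, tail_base = tail_base,
                           tail_len = tail_len, body_orientation = orientation)
  })
  list(locus = locus, spec = spec, pair = build_alleles(locus, spec))
}
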