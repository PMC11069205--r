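#' @importFrom stats median
#' @importFrom utils adist head tail write.table read.table combn modifyList
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin character-in / character-out wrapper around
#' [Biostrings::reverseComplement()].
#'
#' @param x A character vector of DNA sequences (strict ACGT).
#' @return A character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

assert_dna <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x) || !is.character(x))
    stop(what, " must be a single character string", call. = FALSE)
  if (nchar(x) > 0L && grepl("[^ACGT]", x))
    stop(what, " contains non-ACGT characters", call. = FALSE)
  invisible(x)
}

random_dna <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

substr1 <- function(x, from, to) {
  if (to < from) "" else substr(x, from, to)
}

## ---- CIGAR-style op lists --------------------------------------------------

#' Parse a CIGAR-style operation string
#'
#' Only the four op kinds used by this package (M, I, D, S) are accepted.
#'
#' @param cigar A single CIGAR string, e.g. `"50M353I50M"`.
#' @return A data.frame with columns `kind` and `len`.
#' @export
cigar_ops <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar)) stop("empty op list", call. = FALSE)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDS]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar))
    stop("malformed op string: ", cigar, call. = FALSE)
  data.frame(kind = substr(toks, nchar(toks), nchar(toks)),
             len = as.integer(substr(toks, 1L, nchar(toks) - 1L)))
}

#' @rdname cigar_ops
#' @param kind,len Parallel vectors of op kinds and lengths.
#' @export
ops_to_cigar <- function(kind, len) paste0(len, kind, collapse = "")

## query (read) bases consumed by an op list
query_width <- function(ops) sum(ops$len[ops$kind %in% c("M", "I", "S")])
## reference bases consumed by an op list
ref_width <- function(ops) sum(ops$len[ops$kind %in% c("M", "D")])
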