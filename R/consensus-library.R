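## Mobile-element consensus library handling and body classification.

#' Read a consensus element library from FASTA
#'
#' The first whitespace-delimited token of each FASTA header is used as the
#' family label; the remainder of the header is kept as a description.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `family`, `sequence`, `description`.
#' @export
read_consensus_library <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty consensus library: ", path, call. = FALSE)
  hdr <- names(ss)
  fam <- sub("\\s.*$", "", hdr)
  if (anyDuplicated(fam)) stop("duplicate family labels in library", call. = FALSE)
  data.frame(family = fam,
             sequence = as.character(ss),
             description = sub("^\\S+\\s*", "", hdr),
             row.names = NULL)
}

#' The bundled synthetic consensus library
#'
#' Ships three entries: a 282-bp AluYa5-like body (beginning with the
#' canonical `GGCCGGGCGCGGTGG` opening), an AluYb8-like decoy derived from it
#' by ~15% divergence, and a random L1-like fragment decoy.  These are
#' synthetic consensus-like sequences constructed for simulation and testing,
#' not database consensus sequences.
#'
#' @return A data.frame as returned by [read_consensus_library()].
#' @export
default_consensus_library <- function() {
  read_consensus_library(system.file("extdata", "synthetic_consensus_elements.fa",
                                     package = "meiscreen", mustWork = TRUE))
}

#' Classify an element body against a consensus library
#'
#' Aligns the body globally with free end gaps (ends-free overlap alignment,
#' match +1 / mismatch -1 / gap -2) against every library entry and its
#' reverse complement.  Identity is matches divided by aligned columns; the
#' best-identity family is returned if it reaches `min_identity`.
#'
#' @param body Body sequence.
#' @param library Consensus library data.frame (`family`, `sequence`).
#' @param min_identity Minimum identity in `[0, 1]` to accept a family call.
#' @return A list with `family`, `identity`, `orientation`, or `NULL` if no
#'   entry reaches `min_identity`.
#' @export
classify_body <- function(body, library = default_consensus_library(),
                          min_identity = 0.8) {
  assert_dna(body, "body")
  if (!nzchar(body)) stop("empty body", call. = FALSE)
  if (nrow(library) == 0L) stop("empty consensus library", call. = FALSE)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  best <- NULL
  for (i in seq_len(nrow(library))) {
    for (ori in c("plus", "minus")) {
      subj <- if (ori == "plus") library$sequence[i] else revcomp(library$sequence[i])
      aln <- Biostrings::pairwiseAlignment(
        body, subj, type = "overlap", substitutionMatrix = mat,
        gapOpening = 0, gapExtension = 2)
      cols <- Biostrings::nchar(aln)
      ident <- if (cols == 0L) 0 else Biostrings::nmatch(aln) / cols
      ## ends-free alignment permits short perfect corner overlaps whose
      ## identity is meaningless: require the aligned core to cover at least
      ## half of the shorter sequence, and rank candidates by score (which
      ## rewards long high-identity overlaps), not by identity
      if (cols < 0.5 * min(nchar(body), nchar(subj))) next
      sc <- Biostrings::score(aln)
      if (is.null(best) || sc > best$score)
        best <- list(family = library$family[i], identity = ident,
                     orientation = ori, score = sc)
    }
  }
  if (!is.null(best) && best$identity >= min_identity)
    best[c("family", "identity", "orientation")]
  else NULL
}
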