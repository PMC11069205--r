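## Pedigree-based phase inference for two variants, autosomal-recessive
## segregation checking, and STR shared-haplotype (founder) analysis.

#' Construct/validate a pedigree
#'
#' @param individuals data.frame with columns `id`, `father`, `mother`
#'   (`NA` for founders or parents outside the pedigree) and logical
#'   `affected`.
#' @return The validated data.frame with class `pedigree`.
#' @export
pedigree <- function(individuals) {
  stopifnot(all(c("id", "father", "mother", "affected") %in% names(individuals)))
  if (anyDuplicated(individuals$id)) stop("duplicate individual ids", call. = FALSE)
  for (col in c("father", "mother")) {
    known <- !is.na(individuals[[col]])
    ## parents may be named without being rows; keep only resolvable links
    if (any(known & !individuals[[col]] %in% individuals$id))
      stop("parent reference does not resolve: ",
           paste(setdiff(individuals[[col]][known], individuals$id), collapse = ", "),
           call. = FALSE)
  }
  ## topological order / cycle check
  order <- character(0); left <- individuals$id
  repeat {
    ready <- vapply(left, function(i) {
      r <- individuals[individuals$id == i, ]
      all(is.na(c(r$father, r$mother)) | c(r$father, r$mother) %in% order)
    }, TRUE)
    if (!any(ready)) {
      if (length(left)) stop("pedigree contains a cycle", call. = FALSE)
      break
    }
    order <- c(order, left[ready]); left <- left[!ready]
    if (!length(left)) break
  }
  out <- individuals[match(order, individuals$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

geno_copies <- c(absent = 0L, het = 1L, hom = 2L)

## all (v1,v2)-haplotype pairs consistent with an individual's genotype
## (NA genotype = unconstrained); each haplotype is a 2-bit vector
hap_pairs_for <- function(g1, g2) {
  opts <- list()
  for (a1 in 0:1) for (a2 in 0:1) for (b1 in 0:1) for (b2 in 0:1) {
    if (!is.na(g1) && a1 + b1 != geno_copies[[g1]]) next
    if (!is.na(g2) && a2 + b2 != geno_copies[[g2]]) next
    opts[[length(opts) + 1L]] <- list(h1 = c(a1, a2), h2 = c(b1, b2))
  }
  opts
}

#' Infer the phase of two variants from pedigree segregation
#'
#' Exhaustively enumerates all assignments of the two variants to parental
#' haplotypes and all parental transmissions consistent with the observed
#' genotypes (recombination between the variants and de novo events are not
#' modeled).  If every consistent configuration places the two variants on
#' opposite haplotypes of each doubly heterozygous individual the phase is
#' `trans`; if always on the same haplotype, `cis`; otherwise `unknown`.
#' No consistent configuration at all sets the `conflict` flag.
#'
#' @param ped A [pedigree()].
#' @param genotypes data.frame with columns `id`, `v1`, `v2`; carrier states
#'   in `absent`/`het`/`hom` (`NA` = not genotyped).
#' @return A list with `phase` (`"cis"`, `"trans"` or `"unknown"`) and
#'   logical `conflict`.
#' @export
infer_phase <- function(ped, genotypes) {
  ped <- pedigree(ped)
  if (!all(genotypes$id %in% ped$id))
    stop("genotyped individual absent from pedigree: ",
         paste(setdiff(genotypes$id, ped$id), collapse = ", "), call. = FALSE)
  if (nrow(ped) > 12L)
    stop("exhaustive phase enumeration supports up to 12 individuals", call. = FALSE)
  g <- function(id, v) {
    r <- genotypes[genotypes$id == id, v]
    if (length(r) == 0L) NA_character_ else r
  }
  focal <- genotypes$id[!is.na(genotypes$v1) & genotypes$v1 == "het" &
                        !is.na(genotypes$v2) & genotypes$v2 == "het"]
  seen <- c(cis = FALSE, trans = FALSE)
  any_consistent <- FALSE

  ids <- ped$id
  assign_next <- function(i, haps) {
    if (i > length(ids)) {
      any_consistent <<- TRUE
      ph <- vapply(focal, function(id) {
        h <- haps[[id]]
        if (all(h$h1 == c(1L, 1L)) || all(h$h2 == c(1L, 1L))) "cis" else "trans"
      }, character(1))
      if (length(ph)) {
        if (any(ph == "cis")) seen["cis"] <<- TRUE
        if (any(ph == "trans")) seen["trans"] <<- TRUE
      }
      return(invisible())
    }
    id <- ids[i]
    row <- ped[ped$id == id, ]
    g1 <- g(id, "v1"); g2 <- g(id, "v2")
    from_parent <- function(p) {
      if (is.na(p)) list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
      else list(haps[[p]]$h1, haps[[p]]$h2)
    }
    pat <- from_parent(row$father)
    mat <- from_parent(row$mother)
    for (hp in pat) for (hm in mat) {
      if (!is.na(g1) && hp[1] + hm[1] != geno_copies[[g1]]) next
      if (!is.na(g2) && hp[2] + hm[2] != geno_copies[[g2]]) next
      haps[[id]] <- list(h1 = hp, h2 = hm)
      assign_next(i + 1L, haps)
      if (all(seen) && any_consistent) return(invisible())  # can stop early
    }
    invisible()
  }
  assign_next(1L, list())

  phase <- if (!any_consistent) "unknown"
           else if (seen["trans"] && !seen["cis"]) "trans"
           else if (seen["cis"] && !seen["trans"]) "cis"
           else "unknown"
  list(phase = phase, conflict = !any_consistent)
}

#' Check autosomal-recessive segregation of two variants
#'
#' Consistent when every affected individual has a biallelic genotype (both
#' variants, or homozygous for one) and no unaffected individual does.
#'
#' @inheritParams infer_phase
#' @return A list with logical `consistent` and a data.frame `violations`
#'   (`id`, `reason`).
#' @export
check_ar_segregation <- function(ped, genotypes) {
  biallelic <- function(v1, v2) {
    if (is.na(v1) || is.na(v2)) return(NA)
    (v1 == "het" && v2 == "het") || v1 == "hom" || v2 == "hom"
  }
  viol <- list()
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    r <- genotypes[genotypes$id == id, , drop = FALSE]
    if (nrow(r) == 0L) next
    bi <- biallelic(r$v1[1], r$v2[1])
    if (is.na(bi)) next
    if (ped$affected[i] && !bi)
      viol[[length(viol) + 1L]] <- data.frame(id = id,
        reason = "affected without biallelic genotype")
    if (!ped$affected[i] && bi)
      viol[[length(viol) + 1L]] <- data.frame(id = id,
        reason = "unaffected with biallelic genotype")
  }
  viol <- if (length(viol)) do.call(rbind, viol)
          else data.frame(id = character(), reason = character())
  list(consistent = nrow(viol) == 0L, violations = viol)
}

## ---- founder haplotype sharing --------------------------------------------

#' Shared-haplotype analysis of STR genotypes across families
#'
#' Identity-by-state sharing: a marker is shared when one allele value is
#' present in every carrier's genotype pair.  The reported interval is the
#' maximal run of consecutive shared markers containing the anchor marker
#' (the marker nearest `anchor_position`); intervals for every subset of at
#' least two families are reported alongside.
#'
#' @param genotypes data.frame as produced by [simulate_str_families()]:
#'   columns `family`, `individual`, `carrier`, then one `a1/a2` column per
#'   marker.
#' @param markers Marker map data.frame (`name`, `position`), sorted.
#' @param anchor_position Reference position (bp) the interval must contain;
#'   defaults to the midpoint of the EYS exon 32-33 deletion.
#' @return A list with `per_marker` (data.frame `name`, `position`,
#'   `shared_allele`), `interval` (`first`, `last`, `start_bp`, `end_bp`,
#'   `length_bp`, `n_markers`), `families_supported`, and `family_subsets`
#'   (one row per subset of >= 2 families with its own interval).
#' @export
shared_haplotype <- function(genotypes, markers = default_str_markers(),
                             anchor_position = (64764235 + 64820592) / 2) {
  carriers <- genotypes[genotypes$carrier, , drop = FALSE]
  if (nrow(carriers) < 2L || length(unique(carriers$family)) < 2L)
    stop("need >= 2 carriers across >= 2 families", call. = FALSE)

  shared_at <- function(rows, m) {
    sets <- strsplit(rows[[m]], "/", fixed = TRUE)
    common <- Reduce(intersect, sets)
    if (length(common)) sort(common)[1L] else NA_character_
  }
  run_around_anchor <- function(shared) {
    anchor <- which.min(abs(markers$position - anchor_position))
    if (is.na(shared[anchor]))
      return(list(first = NA, last = NA, n = 0L))
    lo <- anchor; hi <- anchor
    while (lo > 1L && !is.na(shared[lo - 1L])) lo <- lo - 1L
    while (hi < nrow(markers) && !is.na(shared[hi + 1L])) hi <- hi + 1L
    list(first = lo, last = hi, n = hi - lo + 1L)
  }
  interval_df <- function(rows) {
    shared <- vapply(markers$name, function(m) shared_at(rows, m), character(1))
    run <- run_around_anchor(shared)
    if (run$n == 0L)
      return(list(shared = shared,
                  interval = data.frame(first = NA_character_, last = NA_character_,
                                        start_bp = NA_real_, end_bp = NA_real_,
                                        length_bp = 0, n_markers = 0L)))
    list(shared = shared,
         interval = data.frame(
           first = markers$name[run$first], last = markers$name[run$last],
           start_bp = markers$position[run$first],
           end_bp = markers$position[run$last],
           length_bp = markers$position[run$last] - markers$position[run$first],
           n_markers = run$n))
  }

  full <- interval_df(carriers)
  fams <- sort(unique(carriers$family))
  subsets <- list()
  if (length(fams) > 2L) {
    for (k in 2:length(fams)) {
      cc <- combn(fams, k)
      for (j in seq_len(ncol(cc))) {
        sub <- carriers[carriers$family %in% cc[, j], , drop = FALSE]
        iv <- interval_df(sub)$interval
        subsets[[length(subsets) + 1L]] <-
          cbind(data.frame(families = paste(cc[, j], collapse = "+"), k = k), iv)
      }
    }
  }
  list(per_marker = data.frame(name = markers$name, position = markers$position,
                               shared_allele = unname(full$shared)),
       interval = full$interval,
       families_supported = fams,
       family_subsets = if (length(subsets)) do.call(rbind, subsets)
                        else data.frame())
}
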