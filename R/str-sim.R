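## Simulation of STR marker genotypes across families sharing a founder
## haplotype around the variant.

#' Default STR marker map flanking EYS
#'
#' The eight microsatellite markers used for founder-haplotype analysis of
#' the EYS locus (D6S1573 .. D6S1681), with approximate GRCh37 chromosome 6
#' positions chosen to span the gene; positions are an approximate synthetic
#' map, adequate for interval lengths but not for fine mapping.
#'
#' @return A data.frame with columns `name` and `position` (bp), ordered by
#'   position.
#' @export
default_str_markers <- function() {
  data.frame(
    name = c("D6S1573", "D6S402", "D6S1658", "D6S1026",
             "D6S1670", "D6S430", "D6S1557", "D6S1681"),
    position = c(57600000, 60900000, 63800000, 64700000,
                 65700000, 66900000, 69200000, 70300000))
}

#' Simulate STR genotypes for families sharing a founder haplotype
#'
#' Every carrier across all families shares one founder allele at each marker
#' inside `shared_markers`; alleles elsewhere are drawn independently per
#' family and individual, and the generator re-draws any outside marker at
#' which the carriers would share an allele by chance, so the planted shared
#' interval is exactly recoverable.  Each family consists of a carrier
#' parent, a non-carrier parent and `n_children` children of random carrier
#' status (at least one carrier child).
#'
#' @param n_families Number of families.
#' @param markers Marker map data.frame (`name`, `position`), sorted by
#'   position.
#' @param shared_markers Names (or indices) of the markers inside the shared
#'   founder interval; may be empty for no forced sharing.
#' @param n_children Children per family.
#' @param seed Integer seed.
#' @return A list with `genotypes` (data.frame: `family`, `individual`,
#'   `carrier`, one `a1/a2` column per marker), `pedigree` (data.frame:
#'   `family`, `id`, `father`, `mother`, `affected`), and `markers`.
#' @export
simulate_str_families <- function(n_families = 4, markers = default_str_markers(),
                                  shared_markers = c("D6S1658", "D6S1026", "D6S1670"),
                                  n_children = 3L, seed = 1L) {
  if (nrow(markers) == 0L) stop("empty marker list", call. = FALSE)
  if (is.unsorted(markers$position, strictly = TRUE))
    stop("markers must be strictly increasing by position", call. = FALSE)
  if (is.numeric(shared_markers)) shared_markers <- markers$name[shared_markers]
  stopifnot(all(shared_markers %in% markers$name))
  nm <- nrow(markers)
  allele_pool <- seq(150L, 260L, by = 2L)
  withr::with_seed(seed, {
    founder <- sample(allele_pool, nm, replace = TRUE)   # the shared haplotype
    draw <- function() sample(allele_pool, 1L)
    geno <- list(); ped <- list()
    for (f in seq_len(n_families)) {
      fam <- sprintf("F%d", f)
      kid_carrier <- sample(c(TRUE, FALSE), n_children, replace = TRUE)
      if (!any(kid_carrier)) kid_carrier[1L] <- TRUE
      ids <- c("father", "mother", sprintf("child%d", seq_len(n_children)))
      carrier <- c(TRUE, FALSE, kid_carrier)
      ## per-family haplotypes: carriers transmit the founder haplotype at the
      ## shared markers and a family-private allele elsewhere
      fam_hap <- ifelse(markers$name %in% shared_markers, founder,
                        sample(allele_pool, nm, replace = TRUE))
      for (i in seq_along(ids)) {
        h1 <- if (carrier[i]) fam_hap else vapply(seq_len(nm), function(m) draw(), 1L)
        h2 <- vapply(seq_len(nm), function(m) draw(), 1L)
        geno[[length(geno) + 1L]] <- data.frame(
          family = fam, individual = paste0(fam, "-", ids[i]),
          carrier = carrier[i],
          t(matrix(paste0(h1, "/", h2))), check.names = FALSE)
        names(geno[[length(geno)]])[-(1:3)] <- markers$name
        ped[[length(ped) + 1L]] <- data.frame(
          family = fam, id = paste0(fam, "-", ids[i]),
          father = if (i > 2) paste0(fam, "-father") else NA_character_,
          mother = if (i > 2) paste0(fam, "-mother") else NA_character_,
          affected = FALSE)
      }
    }
    geno <- do.call(rbind, geno)
    ped <- do.call(rbind, ped)
    ## break chance sharing at non-planted markers so the planted interval is
    ## exactly the maximal shared run
    for (m in setdiff(markers$name, shared_markers)) {
      repeat {
        sets <- strsplit(geno[geno$carrier, m], "/", fixed = TRUE)
        common <- Reduce(intersect, sets)
        if (length(common) == 0L) break
        idx <- which(geno$carrier)
        i <- idx[sample.int(length(idx), 1L)]
        a <- strsplit(geno[i, m], "/")[[1]]
        j <- which(a == common[1L])[1L]
        a[j] <- as.character(sample(setdiff(allele_pool, as.integer(common)), 1L))
        geno[i, m] <- paste0(a[1L], "/", a[2L])
      }
    }
  })
  rownames(geno) <- rownames(ped) <- NULL
  list(genotypes = geno, pedigree = ped, markers = markers)
}
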