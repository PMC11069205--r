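trio <- function() {
  data.frame(id = c("F", "M", "C"), father = c(NA, NA, "F"),
             mother = c(NA, NA, "M"), affected = c(FALSE, FALSE, TRUE))
}

test_that("phase is trans when the variants arrive from different parents", {
  g <- data.frame(id = c("F", "M", "C"),
                  v1 = c("het", "absent", "het"),
                  v2 = c("absent", "het", "het"))
  r <- infer_phase(trio(), g)
  expect_identical(r$phase, "trans")
  expect_false(r$conflict)
})

test_that("phase is cis when both variants co-transmit from one parent", {
  g <- data.frame(id = c("F", "M", "C"),
                  v1 = c("het", "absent", "het"),
                  v2 = c("het", "absent", "het"))
  expect_identical(infer_phase(trio(), g)$phase, "cis")
})

test_that("phase is unknown without informative relatives", {
  g <- data.frame(id = "C", v1 = "het", v2 = "het")
  r <- infer_phase(trio(), g)
  expect_identical(r$phase, "unknown")
  expect_false(r$conflict)
})

test_that("impossible genotype configurations raise the conflict flag", {
  g <- data.frame(id = c("F", "M", "C"),
                  v1 = c("absent", "absent", "hom"),
                  v2 = c("absent", "absent", "absent"))
  r <- infer_phase(trio(), g)
  expect_true(r$conflict)
  expect_identical(r$phase, "unknown")
})

test_that("genotyped individuals must exist in the pedigree", {
  g <- data.frame(id = "X", v1 = "het", v2 = "het")
  expect_error(infer_phase(trio(), g), "absent from pedigree")
})

test_that("phase inference equals an independent exhaustive enumeration", {
  withr::local_seed(81)
  states <- c("absent", "het", "hom")
  for (rep in 1:40) {
    n_kids <- sample(1:4, 1)
    ped <- data.frame(
      id = c("F", "M", paste0("K", seq_len(n_kids))),
      father = c(NA, NA, rep("F", n_kids)),
      mother = c(NA, NA, rep("M", n_kids)),
      affected = FALSE)
    ids <- sample(ped$id, sample(2:nrow(ped), 1))
    g <- data.frame(id = ids,
                    v1 = sample(states, length(ids), TRUE),
                    v2 = sample(states, length(ids), TRUE))
    got <- infer_phase(ped, g)
    exp <- oracle_phase_enum(ped, g)
    expect_identical(got$phase, exp$phase)
    expect_identical(got$conflict, exp$conflict)
  }
})

test_that("AR segregation requires biallelic affecteds and no biallelic unaffecteds", {
  ped <- data.frame(
    id = c("F", "M", "A1", "A2", "A3", "U1"),
    father = c(NA, NA, "F", "F", "F", "F"),
    mother = c(NA, NA, "M", "M", "M", "M"),
    affected = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  g <- data.frame(
    id = ped$id,
    v1 = c("het", "absent", "het", "het", "het", "het"),
    v2 = c("absent", "het", "het", "het", "het", "absent"))
  r <- check_ar_segregation(ped, g)
  expect_true(r$consistent)
  expect_identical(nrow(r$violations), 0L)

  # an unaffected compound heterozygote is a violation
  g$v2[g$id == "U1"] <- "het"
  r2 <- check_ar_segregation(ped, g)
  expect_false(r2$consistent)
  expect_identical(r2$violations$id, "U1")

  # homozygosity for a single variant also counts as biallelic
  g3 <- data.frame(id = "A1", v1 = "hom", v2 = "absent")
  r3 <- check_ar_segregation(ped, g3)
  expect_true(r3$consistent)

  # an affected carrying one het only is a violation
  g4 <- data.frame(id = "A1", v1 = "het", v2 = "absent")
  expect_false(check_ar_segregation(ped, g4)$consistent)
})

test_that("shared haplotype recovers the planted founder interval", {
  sim <- simulate_str_families(seed = 82)
  sh <- shared_haplotype(sim$genotypes, sim$markers)
  expect_identical(sh$interval$first, "D6S1658")
  expect_identical(sh$interval$last, "D6S1670")
  expect_identical(sh$interval$n_markers, 3L)
  expect_identical(sh$interval$length_bp, 65700000 - 63800000)
  orc <- oracle_shared_run(sim$genotypes, sim$markers, 64792413.5)
  expect_identical(sh$interval$n_markers, orc$n)
  expect_identical(sh$interval$first, orc$first)
  expect_identical(sh$interval$length_bp, orc$length_bp)
  # family subsets can only extend the interval
  expect_true(all(sh$family_subsets$n_markers >= sh$interval$n_markers))
})

test_that("shared haplotype is invariant to allele order and non-carriers", {
  sim <- simulate_str_families(seed = 83)
  sh <- shared_haplotype(sim$genotypes, sim$markers)

  flip <- sim$genotypes
  for (m in sim$markers$name) {
    parts <- strsplit(flip[[m]], "/", fixed = TRUE)
    flip[[m]] <- vapply(parts, function(p) paste0(p[2], "/", p[1]), "")
  }
  expect_identical(shared_haplotype(flip, sim$markers)$interval, sh$interval)

  extra <- sim$genotypes[1, ]
  extra$individual <- "stranger"; extra$carrier <- FALSE
  for (m in sim$markers$name) extra[[m]] <- "999/998"
  expect_identical(shared_haplotype(rbind(sim$genotypes, extra),
                                    sim$markers)$interval, sh$interval)
})

test_that("degenerate sharing cases behave", {
  markers <- default_str_markers()
  base <- data.frame(family = c("F1", "F2"), individual = c("a", "b"),
                     carrier = TRUE)
  # no common allele anywhere
  none <- base
  for (m in markers$name) none[[m]] <- c("100/102", "104/106")
  sh0 <- shared_haplotype(none, markers)
  expect_identical(sh0$interval$n_markers, 0L)
  expect_true(all(is.na(sh0$per_marker$shared_allele)))

  # identical homozygotes share the full map
  all8 <- base
  for (m in markers$name) all8[[m]] <- c("100/100", "100/100")
  sh1 <- shared_haplotype(all8, markers)
  expect_identical(sh1$interval$n_markers, 8L)

  expect_error(shared_haplotype(none[none$family == "F1", ], markers),
               ">= 2 carriers")
})
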