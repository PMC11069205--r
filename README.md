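# meiscreen

Characterization of structural variants in a disease gene from long-read
evidence, and junction-probe screening of short-read cohorts — built around
the *EYS* AluYa5 insertion and exon 32–33 deletion that cause autosomal
recessive retinitis pigmentosa, and usable for any locus you can
characterize the same way.

## What it does

A new Alu insertion created by target-primed reverse transcription has a
stereotyped anatomy on the genome:

```
reference ... [TSD] | [element body] [poly-A tail] [TSD copy] | reference ...
```

Short-read pipelines routinely miss these events (junction-chimeric reads
soft-clip or fail to map); long reads span them completely. `meiscreen`
implements the full workflow as tested R functions:

* **Simulation** — rebuild the wild-type/mutant allele pair for an
  insertion or deletion from printed sequences (`eys_alu_fixture()`,
  `build_alleles()`), and simulate seeded short/long reads, cohorts and STR
  family genotypes with truthful alignment op lists.
* **Long-read calling** — per-read insertion/deletion signatures from
  CIGAR-style ops, single-linkage clustering into calls with median
  breakpoints (`collect_signatures()`, `cluster_signatures()`), medoid +
  majority consensus of the inserted sequence, and repeat-context
  annotation of breakpoints from BED (`annotate_repeat_context()`).
* **Insertion decomposition** — TSD (longest exact shared flank string,
  with principled handling of homopolymer-ambiguous boundary bases), poly-A/T
  tail (purity-window run detection), element body classified against a
  consensus library by ends-free alignment (`decompose_insertion()`),
  HGVS-style naming and coding-consequence translation.
* **Probe design & screening** — allele-diagnostic junction k-mers with
  reverse-complement closure and homopolymer capping
  (`design_junction_probes()`), exact-substring specificity validation,
  grep-equivalent patterns (`emit_patterns()`), and per-sample read
  counting with VAF = mut/(mut+wt) genotype calls across cohorts
  (`scan_stream()`, `screen_cohort()`).
* **Soft-clip evidence** — clip clustering at a junction, clipped-base
  consensus versus the expected insert end, clipped-read percentage and
  coverage-drop statistics (`collect_clips()`, `clip_summary()`).
* **Segregation** — exhaustive pedigree phase inference (cis/trans) for two
  variants, autosomal-recessive segregation checking, and identity-by-state
  STR founder-haplotype intervals across families (`infer_phase()`,
  `shared_haplotype()`).

## Worked example

Characterize the insertion from simulated heterozygous long reads, then
screen a small cohort:

```r
library(meiscreen)

fx   <- eys_alu_fixture()
pair <- build_alleles(fx$insertion_locus, fx$insertion)

reads <- simulate_reads(pair, "ref/mut", depth = 20, read_len = 1000,
                        mode = "long", seed = 42)
res <- run_characterize(reads, fx$insertion_locus)
res$calls[, c("kind", "ref_start", "length", "support", "ci", "hgvs")]
#>   kind ref_start length support ci                      hgvs
#> 1  INS  64430524    353      10  0 g.64430524_64430525ins353
```

The call lands on the last reference base before the insertion
(chr6:64,430,524) with 10 supporting reads and a ±0 confidence interval,
and its decomposition recovers the published anatomy:

```r
m <- res$mei_reports[[1]]
sprintf("family %s, identity %.2f, body %d bp, tail %d x %s, TSD %d bp (%s)",
        m$family, m$body_identity, m$body_len, m$tail_len, m$tail_base,
        m$tsd_len, revcomp(m$tsd_sequence))
#> "family AluYa5, identity 1.00, body 282 bp, tail 56 x A, TSD 15 bp (AACATTGTATCCTTC)"
```

The published screening probes validate against the reconstructed alleles
and emit ready-to-use grep alternations:

```r
probes <- check_specificity(eys_alu_probe_set(), pair$mut, pair$wt)
emit_patterns(probes, "fastq_grep")
#> $WT
#> [1] "ATTAGAAGGATACAATGTTTATG\\|CATAAACATTGTATCCTTCTAAT"
#> $MUT
#> [1] "GAAGGATACAATGTTGGCCGGGC\\|GCCCGGCCAACATTGTATCCTTC\\|ACATTGTATCCTTCTTTTTTTT\\|AAAAAAAAGAAGGATACAATGT"
```

Screening a simulated 10-sample cohort with one planted heterozygote
recovers exactly that carrier:

```r
dir   <- tempfile()
gts   <- rep("ref/ref", 10); gts[4] <- "ref/mut"
truth <- simulate_cohort(gts, pair, dir, depth = 30, read_len = 100, seed = 42)
rep   <- screen_cohort(truth$file, probes)
rep[1:5, 1:5]
#>   sample_id mut_reads wt_reads     vaf genotype
#> 1 sample001         0       33 0.00000  ref/ref
#> 2 sample002         0       28 0.00000  ref/ref
#> 3 sample003         0       18 0.00000  ref/ref
#> 4 sample004        19       13 0.59375  ref/mut
#> 5 sample005         0       26 0.00000  ref/ref
attr(rep, "n_carriers")
#> [1] 1
```

A sample with no mutant-junction reads is `ref/ref`; sample 4's VAF of
0.59 (19 mutant of 32 informative reads) calls `ref/mut`.

See the vignette (`vignettes/mei-characterization.Rmd`) for the model,
parameter meanings and design rationale.

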