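---
title: "Characterizing mobile element insertions and screening cohorts with meiscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing mobile element insertions and screening cohorts with meiscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiscreen)
```

## The problem

Mobile element insertions (MEIs) — here an AluYa5 retrotransposon landing in
a coding exon of *EYS*, the major autosomal-recessive retinitis pigmentosa
gene — are notoriously hard to see in short-read sequencing: reads chimeric
across the junction soft-clip or fail to map, so standard pipelines report
nothing, and the only traces are clipped bases and a slight coverage dip.
Long reads span the whole event and reveal its full anatomy: an element
body, a poly-A/T homopolymer tail, and a target-site duplication (TSD)
created by target-primed reverse transcription. Once the insertion is
characterized at nucleotide resolution, a cohort can be screened for it with
nothing more than exact junction k-mers applied to raw reads — the
"grep screen" this package generalizes. The same locus also carries a
recurrent ~56.4-kb deletion of exons 32–33; the package characterizes it
from long-read deletion signatures and assesses founder sharing of flanking
STR haplotypes across families.

`meiscreen` implements that whole arc as tested, reusable functions:
simulation of the alleles and reads, decomposition of insertion calls,
breakpoint clustering, probe design and specificity checking, cohort
screening with genotype calls, soft-clip quantification, and pedigree/STR
analysis.

## The allele model and its coordinates

All user-facing coordinates are 1-based inclusive reference coordinates
(HGVS convention); a `locus_config()` maps a local simulated sequence onto
them and `local_to_ref()`/`ref_to_local()` are tested explicitly.
Insertions follow the TPRT layout on the construction (plus) strand:

* plus-orientation element: `body + A-tail + TSD` inserted after a
  reference position whose 5' context ends with the same TSD;
* minus-orientation element: `T-tail + revcomp(body) + TSD`.

The bundled EYS fixture (`eys_alu_fixture()`) rebuilds both published
variants from their printed sequences: the 15-bp TSD
(`GAAGGATACAATGTT`, i.e. `AACATTGTATCCTTC` on the transcript strand), the
printed four-base junction context `ATTA … TATG`, a 282-bp element body
beginning `GGCCGGGC`, a 56-bp poly-A tail, the insertion point after
chr6:64,430,524, and the deletion chr6:64,764,235–64,820,592 (56,358 bp ≈
56.4 kb). Flanks beyond the printed bases are seeded-random and kept free
of all probe sequences. The insertion and deletion are ~334 kb apart, so
the fixture carries two locus configurations (a ~2-kb insertion locus and a
~58-kb deletion locus) rather than one giant random interval.

Note on insert length: the component sum 282 + 56 + 15 = 353 bp is what the
fixture produces and what the pipeline calls; published descriptions of
this event round it to ~352 bp, and the exact value depends on how the
element accession boundaries are drawn.

The element body comes from `inst/extdata/synthetic_consensus_elements.fa`
— *synthetic* consensus-like sequences (an AluYa5-like 282-mer, an
AluYb8-like decoy at ~85% identity to it, mimicking the true Ya5/Yb8
similarity, and a random L1-like fragment). They support every structural
property of the pipeline but are not database consensus sequences, which is
why the protein-level consequence of the real insertion (a count of
aberrant residues before a premature stop) is computed by
`coding_consequence()` but never asserted against a literature value.

## Decomposition: TSD, tail, body

`decompose_insertion()` works in a fixed order: TSD, then tail, then body.

**TSD** (`detect_tsd()`): the longest exact string shared between the
insert end and the adjacent reference flank, testing both placements
(insert ends with it / insert starts with it), ties to the 3' placement.
Defaults `min_tsd = 5`, `max_tsd = 50` — TPRT duplications are typically
5–20 bp. Matching is exact: tolerance for mismatches adds ambiguity with no
benefit at these lengths.

One refinement matters in practice: when the base at the element-side
boundary of the maximal shared string equals the insert base just beyond
it, that base cannot be attributed — in the EYS fixture the reference base
5' of the TSD is an A and the insert base 5' of the TSD copy is the poly-A
tail, so the *maximal* shared suffix is 16 bp. The decomposition trims such
ambiguous boundary bases off the TSD (assigning them to the tail side),
which reproduces the conventional 15-bp/56-bp annotation and keeps the
partition identifiable.

**Tail** (`detect_poly_tail()`): the longest terminal window that ends on
the run base and keeps its fraction at or above `purity = 0.9`
(`min_len = 10`); the run base must be A or T. The window search equals a
brute-force enumeration over all terminal windows and is tested against
one. The tail is searched at the end adjacent to the detected TSD; if
nothing qualifies there it falls back to the opposite end, which is where
the homopolymer of a minus-orientation element lies under the construction
convention above.

**Body** (`classify_body()`): whatever remains, aligned ends-free
(match +1, mismatch −1, gap −2) against every library entry and its reverse
complement. Candidates must cover at least half of the shorter sequence —
ends-free alignment otherwise admits one-base "corner" overlaps with
meaningless 100% identity — and are ranked by alignment score; the winner
is reported with identity = matches / aligned columns and accepted at
`min_identity = 0.8`. Identity is 1.0 exactly when the body is an exact
substring-alignment of an entry.

### Canonical specs and what the round-trip shows

The simulator's random spec generator (`random_insertion_spec()`) only emits
*canonical* specs: the body's tail-adjacent terminus carries a 12-base
window free of the tail base, the TSD does not begin with the insert base
adjacent to its copy, and the reference base 5' of the TSD differs from
that base. These are not conveniences but identifiability conditions — a
trailing tail-base base of the body, or a TSD starting with the tail base,
is mathematically attributable to either component, so no decomposition
could recover "the" planted lengths. The 12-base buffer follows from the
purity-window arithmetic: with purity 0.9 and tails up to 80 bp, no
qualifying window can jump a tail-base-free gap of that size. Under these
conditions the decomposition round-trips 100/100 random specs exactly
(TSD, tail and body lengths, tail base, orientation); real data additionally
contains sequencing error, truncated elements, and non-canonical junctions,
so the round-trip demonstrates correctness of the machinery, not universal
resolvability.

## Long-read calling

`collect_signatures()` replays what an SV caller extracts from alignments:
one signature per explicit insertion/deletion op of at least
`min_sv_len = 30` bases, positioned by walking match/deletion ops from the
mapped start. There is no realignment or split-read rescue — the simulator
emits truthful op lists, and alignment itself is out of scope.
`cluster_signatures()` merges same-kind signatures within `window = 50` bp
by single linkage, reports the (low) median position and length, a
confidence interval as the maximal deviation from the median, and drops
clusters below `min_support = 3`. On error-free reads the calls sit exactly
on the construction coordinates with CI ±0, and clustering is invariant to
input order. `consensus_insert()` polishes the inserted sequence by
majority vote over a medoid alignment (medoid = minimum summed edit
distance, ties by input order; column ties resolved toward the medoid
base). `annotate_repeat_context()` reports the repeat containing a
breakpoint and the nearest repeat on each side with gap distances; BED
input is 0-based half-open on disk and converted at the boundary.

## Probe design and cohort screening

`design_junction_probes()` emits, for each diagnostic junction, the
plus-strand k-mer and its reverse complement. The two diagnostic mutant
junctions are reference|element and element|TSD-copy — the TSD copy and
everything after it are reference-identical, so a k-mer across the literal
insert-end|reference boundary would match the wild type. Probes are
centered by default (⌈k/2⌉ bases 5'); a side that is a homopolymer run at
least as long as its allocation is capped at `homopolymer_cap = 8` bases
(matching the 8 A/T bases of the published poly-tail probes). Published
probe layouts are not always centered — the original 5'-junction probe
splits 15+8, and the poly-tail probes are 22-mers — so explicit per-side
lengths are accepted and `eys_alu_probe_set()` ships the six published
sequences verbatim. `check_specificity()` validates MUT probes as present
in the mutant allele and absent (both strands, exact substring) from the
wild type and any background; designed probes and user-supplied probes go
through the same check.

`scan_stream()` counts matching *reads* per allele class, equivalent to
`grep -c` line counting on FASTQ sequence lines (probes already encode both
strands); a read matching both classes counts only as a conflict. Matching
is exact and case-insensitive — one sequencing error defeats a probe, a
sensitivity limitation this screening strategy intrinsically shares with
its command-line ancestor. `call_genotype()` applies
VAF = mut/(mut + wt) with defaults `min_total = 10`, `min_mut_reads = 3`,
`het_vaf_min = 0.2`, `hom_vaf_min = 0.8`; the original screen reported no
thresholds (it observed zero carrier matches), so these are conventional
diagnostic settings, fully configurable. `screen_cohort()` isolates
per-sample I/O failures into `no_call` rows rather than aborting a run.

## Soft-clip evidence

`collect_clips()` groups reads whose clip boundary falls within
`window = 10` bp of the candidate site, keeping clips of at least
`min_clip_len = 8` bases (shorter clips are uninformative against a 282-bp
element). `clip_summary()` reports the clipped-read percentage (rounded to
integer for display), a boundary-anchored majority consensus of the clipped
bases compared against the expected insert end at 90% identity, and
`coverage_drop = 1 − in/flank` floored at zero, with fixed windows (±25 bp
at the junction; two 100-bp windows 200 bp away) so the statistic is
reproducible. Note that the simulator aligns the reference-side portion of
every junction read, so simulated data shows no systematic coverage dip;
the dip in real data comes from aligner behavior on chimeric reads, and the
tests therefore exercise the statistic's arithmetic, not its magnitude.

## Pedigree phase and founder haplotypes

`infer_phase()` decides whether two variants are in cis or trans by
exhaustive enumeration of haplotype assignments and parental transmissions
consistent with the observed genotypes (no recombination between the
variants, no de novo events — the variants here are 334 kb apart in one
gene). Enumeration subsumes the usual trio rules (variant from each parent
⇒ trans; both from one parent ⇒ cis) and returns `unknown` with a conflict
flag when no consistent configuration exists; pedigrees are capped at 12
individuals, ample for clinical families. The suite checks it against an
independently written enumerator on randomized nuclear pedigrees of up to
six members. `check_ar_segregation()` applies the recessive rule directly:
every affected biallelic, no unaffected biallelic.

`shared_haplotype()` uses identity-by-state sharing — one allele value
present in every carrier's genotype pair — per marker, and reports the
maximal run of consecutive shared markers containing the anchor marker
(nearest the deletion midpoint by default), plus the same interval for
every family subset, mirroring how founder intervals extend in subsets of
families. No IBD probability model is used. The default eight-marker map
uses approximate chromosome 6 positions spanning *EYS*; interval lengths
are realistic (the planted default span is 1.9 Mb) but the map is synthetic.
`simulate_str_families()` plants a founder haplotype across families and
actively breaks chance sharing at non-planted markers, so the planted
interval is exactly the maximal shared run.

## Orchestration and reproducibility

`run_characterize()` chains signatures → clusters → insert consensus →
decomposition → repeat context; `run_screen()` chains design → specificity
→ scanning → genotyping and refuses to screen with any unvalidated probe.
Both write TSV outputs and a JSON run manifest (inputs, parameters, seed,
package version) when given an output directory. The package's interface is
its exported functions — the stages map one-to-one onto `simulate_*`,
`run_characterize`, `design_junction_probes`, `run_screen`,
`collect_clips`/`clip_summary`, and `infer_phase`/`shared_haplotype` — and
`scripts/acceptance.R` is a worked end-to-end driver.

Every stochastic step takes an explicit seed (`withr::with_seed`, so global
RNG state is untouched), and seeded runs are byte-identical down to the
FASTQ files. Problem sizes used in the shipped checks — ~100–200 long reads
per calling run, cohorts of up to 327 samples at 5× with 100-bp reads,
100-spec decomposition round-trips — were chosen to mirror the study
conditions at desk scale.

## Known limitations

* Substitution-only error model with constant dummy qualities; no indel
  errors, no nanopore error profile, no quality-aware consensus.
* Exact-substring screening cannot see probe-disrupting sequencing errors
  or nearby polymorphisms; VAFs are raw count ratios without likelihoods.
* No genome-wide MEI discovery: the pipeline characterizes a locus it is
  pointed at.
* 5'-truncation modeling for LINE-1/SVA, methylation, and real-genome
  coordinate liftover are out of scope; the coordinate map is local.
* The consensus library is synthetic; family labels are meaningful relative
  to it, and protein-level consequences of real elements require the true
  element sequence.
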