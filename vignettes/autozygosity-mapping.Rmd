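---
title: "Mapping a recessive trait from homozygosity runs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive trait from homozygosity runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The mapping problem

A fully penetrant recessive mutation that arose once in a closed breeding
population sits on a single founder haplotype. Every affected individual
carries two copies of that haplotype around the causal site — it is
*autozygous* there — so a cohort of affected animals is simultaneously
homozygous across a long stretch of markers flanking the locus. When the
cohort is a family-structured breed, a case–control association study is
fragile (relatedness inflates false positives), but the autozygosity
signal itself is robust and needs no controls: scan the genome for the
longest run of markers at which *all* cases are homozygous, then ask which
rare coding variant, carried homozygously by a sequenced case and absent
from a panel of unrelated genomes, falls inside that run.

`rohmap` implements this strategy end to end, together with a gene-drop
simulator that manufactures studies with known ground truth so that every
stage can be validated.

# Homozygosity scan

For each marker the package computes **observed heterozygosity** in the
case group,

$$H_e = \frac{\#\{\text{called cases that are heterozygous}\}}
             {\#\{\text{called cases}\}},$$

and a marker *qualifies* when $H_e = 0$. Two points deserve emphasis:

* **$H_e$ is per-genotype, not allele-frequency based.** The symbol is
  overloaded in population genetics; here it is the fraction of
  heterozygous genotypes, because the run criterion is "every case
  homozygous", applied genotype by genotype.
* **Missing calls disqualify a marker by default.** A marker with any
  missing case call cannot certify that *all* cases are homozygous, so the
  strict default requires every case called (`min_called = `number of
  cases). The `min_called` parameter relaxes this for noisier chips.

Runs are maximal stretches of consecutive qualifying markers. They never
cross a chromosome boundary, must contain at least `min_run_snps` markers
(default 20 — short homozygous runs abound genome-wide, and the default is
purely a noise floor), and are ranked by SNP count, ties broken by base-pair
span, then genomic order. Span is **1-based inclusive**
(`last - first + 1`), the same convention used for every interval in the
package, and the output column is named `span_bp_inclusive` so the
convention travels with the data.

Per-individual homozygosity does not imply that all cases share the *same*
homozygous allele, although autozygosity would force that. The scanner
therefore reports a `shared_allele_consistent` flag per run, and
`scan_params(require_shared_allele = TRUE)` turns the stricter
interpretation into a filter. The default is off: per-individual
homozygosity is the primary criterion, and the shared-allele mode is
offered as the autozygosity-flavoured alternative.

The scanner is validated against a brute-force oracle that enumerates all
maximal qualifying intervals by prefix sums over every (start, end) pair;
the two agree on 1000 random instances of up to 200 markers by 12 samples
in the acceptance suite.

# Case-versus-panel contrast

The second, independent line of evidence: sequence one case and remove
every variant whose alternate allele is seen in a panel of unrelated
genomes. `contrast()` retains records where

1. the case genotype is homozygous for an alternate allele (a causal
   recessive allele absent from controls must be non-reference and
   two-copy in the case — reference-homozygous case genotypes are never
   candidates), and
2. that allele is absent from every panel sample.

Two absence semantics are exposed because genotype-level contrast tools
behave differently from allele-level filters: `allele_absent` (default,
stricter — a panel heterozygote kills the record) and `genotype_absent`
(only an identical panel genotype kills it). The default is the stricter
reading; the genotype mode provably retains a superset, which the test
suite asserts on random fixtures.

Missing panel genotypes count as "not carrying the allele" by default,
matching a naive contrast; `treat_panel_missing_as = "unknown_excludes"`
drops any record with panel missingness for conservative use.
Multi-allelic records are kept intact rather than split — splitting
silently changes genotype semantics — and the test is applied to the
allele the case is homozygous for.

`intersect_region()` applies the mapped region as a final 1-based
inclusive filter on the anchored position (indels qualify via their
anchor). Stage counts (input, case-genotype, private, in-region) are
non-increasing by construction and are carried into the report.

# Consequence annotation

Variants are projected onto transcript models (exon/CDS intervals plus
strand) over a reference sequence. Conventions:

* **Left alignment.** Indels are left-aligned against the reference before
  projection, and the VCF anchor base is not part of the affected
  interval. This makes a "removes N bases" interval description and an
  (N+1)-base VCF REF allele agree exactly.
* **Classification.** SNVs are classified by codon comparison
  (synonymous / missense / stop_gained / stop_lost / start_lost). Pure
  indels fully inside the CDS are `frameshift` when the net length change
  is not a multiple of 3, `inframe_insertion`/`inframe_deletion`
  otherwise. Indels that touch a CDS/intron or CDS/UTR boundary get the
  class `splice_region_unsupported` and no protein arithmetic: splice-fate
  prediction is deliberately out of scope.
* **First affected residue.** The first codon whose *encoded residue*
  differs between wild-type and mutant — not merely the first codon
  overlapping the indel. A shifted frame can initially reproduce
  wild-type residues; the HGVS frameshift rules demand the first changed
  one.
* **Ter numbering.** For a frameshift the mutant is translated from the
  first affected codon to the first stop. `RefPosAltfsTerN` counts the
  stop with the first changed residue as 1, so the mutant stop sits at
  protein position `Pos + N - 1`, and the novel peptide (changed residues
  before the stop) has length `N - 1`. If no stop is reached before the
  transcript end the suffix is `fsTer?`.
* Standard nuclear codon table throughout; minus-strand models are
  handled by reverse-complement projection, and annotating a minus-strand
  transcript is identical to annotating its reverse-complemented
  plus-strand construction (a property the suite checks).

The annotator takes the efficient path — partial translation from the
first affected codon. Its oracle in the acceptance suite is maximally
dumb: apply the edit to the chromosome string, shift all downstream
coordinates, re-extract and fully translate the mutant CDS, and diff the
complete proteins. The two agree on 500 random transcript/indel pairs.

# The synthetic-data generator

The generator manufactures the study the pipeline expects, with truth
recorded at every step. It emulates a young breed in which a recessive
trait was deliberately fixed:

* **Pedigree** (`build_aht_like_pedigree`): one founder female carries a
  single copy of the causal allele; each generation preferentially mates
  carriers and affected dogs ("backcrossing" in breeders' usage,
  `backcross_rate`), unrelated non-carrier founders join the pool in later
  generations (`outcross_rate`), and one carrier male per generation is
  reused as a popular sire (`popular_sire_rate`). Phenotype is fully
  penetrant recessive. Defaults (6 generations, 6 matings of 4 pups per
  generation) were chosen once as a small but realistic breed nucleus;
  real litter sizes and generation counts for any particular breed are
  unknown, and these are free parameters, not estimates.
* **Gene drop** (`gene_drop`): founder homologues receive labelled
  haplotypes; each meiosis recombines under the **Haldane model**
  (crossover count Poisson with mean equal to map length, no
  interference, uniform 1 cM/Mb by default — the simplest defensible
  model). Transmissions at the causal locus are conditioned on the
  causal-allele carriage recorded in the pedigree by choosing the gamete's
  starting phase after the crossover positions are drawn, which samples
  the correct conditional distribution. Chip genotypes are read off the
  haplotypes as alternate-allele dosages over a founder-haplotype pool
  with marker allele frequencies uniform on [0.15, 0.85].
* **Missingness** is applied independently per call, after the drop. The
  default rate is 0: the emulated matrix is the *post-QC informative-call*
  matrix a chip pipeline delivers, and the strict scan would discard
  incomplete markers anyway. Raise `missing_rate` to exercise the
  `min_called` relaxation.
* **Genome scale.** Four autosomes of 4.5/4.0/3.5/3.0 Mb with 250 markers
  each — a deliberate miniature that keeps a full study (reference FASTA
  included) generatable in seconds. One consequence of scaling lengths
  down while keeping 1 cM/Mb: per-meiosis recombination is rare, so the
  rank-1 run typically spans most of the causal chromosome rather than a
  sub-interval. Sex chromosomes are excluded (the emulated signal is
  autosomal; hemizygous males would need separate dosage handling).
* **Reference and transcript** (`make_reference_bundle`): a random genome
  with an 18-exon toy transcript (471 codons) written into it, whose CDS
  is constructed codon-wise so that deleting 4 specific bases in exon 4
  yields Val96GlyfsTer50 — the frameshift-at-96, stop-50-codons-later
  geometry of the motivating mutation, reproduced at toy scale by
  construction rather than by search. The CDS is guaranteed internally
  stop-free in the wild-type frame.
* **Variant file** (`plant_private_frameshift`): the case is homozygous
  for the planted deletion, no panel sample carries it, and background
  variants are shared with the panel at a configurable rate. Private
  homozygous-alternate background variants are placed off the causal
  chromosome, emulating the empirical situation in which a case genome
  carries thousands of private variants of which only one falls inside
  the mapped region. The expected protein consequence of the planted
  deletion is computed at generation time by full mutant-CDS translation
  and stored in the truth record, so the pipeline's arithmetic is checked
  against an independent route.

What the generator does **not** emulate: linkage disequilibrium between
founder haplotypes (marker alleles are drawn independently), genotyping
error beyond missingness, mutation, selection other than the breeding
scheme, and sex chromosomes. Passing tests therefore demonstrate the
correctness of the algorithms under the stated model, not robustness to
chip artefacts or LD structure in real data.

# Coat-genotype rule engine

`predict_coat()` encodes the five-locus pelage genetics as a deterministic
priority list: homozygous FOXI3 duplication is embryonic lethal;
heterozygous FOXI3 duplication gives the semi-dominant CED-type
hairlessness; homozygous SGK3 deletion gives the recessive hairlessness;
otherwise furnishings are dominant (any RSPO2 insertion allele), long coat
is recessive (two FGF5 long alleles), and curl shows only on long coats —
a short-coated curl-allele carrier reports `curl = "masked"` because the
fur is not long enough to express it. Hairless and lethal outcomes mask
the length/curl fields. FGF5 dominance is encoded as recessive-long at the
two-allele level, consistent with long-coated breeds being homozygous; the
shedding-associated MC5R locus and the modifier loci behind variable
hairlessness are deliberately excluded as unsettled. `enumerate_phenotype_table()`
emits all $3^5 = 243$ genotype combinations and is the closure check: no
combination yields a curly short coat, and every genotype maps to exactly
one phenotype.

# Pipeline and reproducibility

`run_pipeline()` chains scan → rank-1 region → contrast → intersect →
annotate and assembles a report with staged counts, per-candidate
consequences and HGVS strings, and provenance (input MD5 sums, package
version, configuration echo). The rank-1 run alone is passed as the
region, mirroring the single dominant region this design produces; an
empty run set yields a `no_mappable_region` report, not an error. The
pipeline is deterministic given its inputs: reruns are byte-identical once
timestamps are excluded.

Problem sizes used by the validation suite — 1000 random scanner
instances, 500 annotator pairs, 100 gene-drop replicates, 3 demo studies —
were chosen as the package's own convergence/coverage trade-off: large
enough that the binomial checks (e.g. ≥ 95 % causal-locus recovery,
carrier×carrier segregation within 3 standard errors of 25 %) are
meaningful, small enough to run routinely.

# Known limitations

* ROH calling is exact-threshold, not likelihood-based: no HMM smoothing
  over genotyping error, which is the trade-off for the transparent
  "every case homozygous" criterion.
* Splice-spanning indels are flagged, never translated.
* The contrast takes genotypes as called; there is no quality
  recalibration or population-frequency weighting.
* Protein-domain coordinates are user-supplied; `domain_overlap()`
  classifies fate (intact / truncated / lost) but does not discover
  domains.
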