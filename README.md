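# rohmap

Autozygosity mapping of recessive Mendelian traits in closed breeding
populations, for geneticists working with family-structured cohorts (dog
breeds being the motivating case) where a case–control GWAS is unreliable.

A recessive mutation that arose once sits on a single founder haplotype,
so every affected individual is homozygous across a long run of SNPs
flanking the causal locus. `rohmap` implements the resulting two-pronged
mapping strategy:

1. **Homozygosity-run scan.** Per marker, observed heterozygosity in the
   affected cohort, *H*ₑ = (# heterozygous called cases)/(# called cases);
   markers with *H*ₑ = 0 qualify, and maximal runs of consecutive
   qualifying markers are tallied (SNP count, inclusive bp span) and
   ranked.
2. **Private-variant contrast.** Variants homozygous-alternate in a
   sequenced case and absent from every genome in a control panel are
   retained, intersected with the rank-1 run, and annotated against
   transcript models — frameshifts get full protein arithmetic and HGVS
   p. notation (`RefPosAltfsTerN`, stop counted with the first changed
   residue as 1).

The package also ships a pedigree **gene-drop simulator** (Haldane
recombination, founder haplotypes, a planted private frameshift with
recorded truth) that generates complete synthetic studies for validation,
and a deterministic **coat-genotype rule engine** for the five pelage
genes (RSPO2, FGF5, KRT71, FOXI3, SGK3).

## Worked example

Generate a synthetic study (pedigree with ≥ 8 hairless dogs, chip
genotypes, reference + 18-exon transcript, multi-sample VCF with a planted
private 4-bp frameshift and a 20-genome panel), then run the full
pipeline:

```r
library(rohmap)
demo <- make_demo(seed = 1, dir = "demo1")
report <- run_pipeline(demo$config)
print(report)
```

```
candidate_report: rank-1 region chr2:568258-3550319 (175 SNPs, 2982062 bp)
stages: input=401 -> case_genotype=119 -> private=11 -> in_region=1
1 candidate annotation row(s)
  chr2:2001990 TGTTA>T  SGK3TOY.1  frameshift  p.Val96GlyfsTer50
```

Reading: the scan found a ~3 Mb run of 175 SNPs at which all 11 cases are
homozygous; of 401 variants in the VCF, 119 are homozygous-alternate in
the case, 11 of those are absent from all 20 panel genomes, and exactly
one private variant lies inside the mapped run — the planted deletion
(VCF anchor representation `TGTTA>T`, i.e. 4 bases removed). It shifts the
toy kinase transcript's reading frame at Val96, producing 49 novel
residues and a premature stop: p.Val96GlyfsTer50. This matches the truth
record the generator stored (`demo$truth$planted$hgvs_p`).

The same steps are scriptable from a shell via the thin CLI in
`inst/cli/rohmap` (verbs `demo`, `run`, `scan`, `contrast`, `annotate`,
`coat`).

## Package layout

- `R/` — simulator (`build_aht_like_pedigree`, `gene_drop`,
  `make_reference_bundle`, `plant_private_frameshift`, `make_demo`),
  readers/writers (tab-delimited genotype matrix and pedigree dialects,
  VCF 4.2 via vcfR, FASTA via Biostrings, GFF3 via rtracklayer; plain or
  gzipped), the scan (`case_heterozygosity`, `find_runs`, `rank_report`,
  `he_profile_plot`), the contrast (`contrast`, `intersect_region`,
  `contrast_report`), annotation (`annotate_variant`, `hgvs_protein`,
  `domain_overlap`, `interval_length`), coat rules (`predict_coat`,
  `enumerate_phenotype_table`) and the orchestrator (`run_pipeline`).
- `vignettes/autozygosity-mapping.Rmd` — the model, conventions and
  design decisions in detail.
- `tests/testthat/` — unit, property and acceptance tests, including
  brute-force oracles for the run scanner and the consequence annotator.
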