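# fbpconcord

Concordance analysis of paired genome annotations for the anthocyanin
branch of the flavonoid biosynthesis pathway (FBP): chalcone synthase
(CHS), chalcone isomerase (CHI), flavanone 3-hydroxylase (F3H),
flavonoid 3'-monooxygenase (F3'H), flavonoid 3',5'-hydroxylase
(F3'5'H), dihydroflavonol 4-reductase (DFR) and anthocyanidin synthase
(ANS).

Gene copy number — the raw material of comparative studies of pathway
evolution — is only as reliable as the underlying annotation.  When a
genome carries two independent annotations (a unified pipeline such as
NCBI's versus a genome-specific project pipeline), `fbpconcord`
measures how well they agree for these seven enzyme families and
reconciles them into one merged gene set.

## Method

For each species with two annotation sources A and B:

1. **Normalize** each source: infer coding sequences as the longest
   open reading frame (minimum 300 nt), collapse transcript variants to
   the longest per locus, drop overly ambiguous records.
2. **Mine homologs** of each enzyme with a relaxed Smith–Waterman
   search (match +1, mismatch −1, `E ≤ 1e−50` under Karlin–Altschul
   statistics, `E = K·m·n·e^{−λS}` with `λ = log 3` for ±1 scoring).
3. **Classify** cross-source reciprocal best hits (RBH) within each
   (enzyme, species) family: *perfect pairs* are RBHs with identical
   CDS strings, *imperfect pairs* are all other RBHs, everything else
   is *unpaired*; unpaired annotations identical to another gene of the
   same source are excluded as redundant.
4. **Rescue**: build per-enzyme codon-aware alignments, trim to
   conserved codon blocks (b2/b5 = 0.5, b4 = 5 codons), build
   neighbor-joining trees on GTR(+Γ) distances with codon-column
   bootstraps, and reclassify same-species cross-source cherries of
   unpaired genes as imperfect pairs.
5. **Summarise**: concordance totals (with the accounting identity
   `totals_A = perfect + imperfect + unpaired_A + excluded_A`),
   per-enzyme × per-species copy-number matrices with discrepancy and
   zero flags, and mean ± SD coding-sequence lengths per category.

A birth–death gene-family simulator with K80/JC sequence evolution
generates paired, independently corrupted annotation sources (missed
genes, UTR/coding-boundary shifts, in-frame truncations, redundant
variants, identical in-source duplicates) together with a ground-truth
table, so the whole pipeline can be validated end to end.

## Worked example

Simulate six Solanaceae species with two corrupted annotation sources
and run the full analysis:

```r
library(fbpconcord)
tree <- ape::keep.tip(default_species_tree(),
                      default_species_tree()$tip.label[1:6])
cfg <- simulation_config(species_tree = tree, seed = 42)
sim <- simulate_annotation_pair(cfg)
res <- concordance_analysis(sim$source_a, sim$source_b, sim$seeds,
                            bootstraps = 100)
res$report
#> Annotation concordance
#>   source A total: 47   source B total: 46
#>   shared pairs:   41 (perfect 34, imperfect 7)
#>   unpaired:       A 3, B 4
#>   excluded (redundant): A 3, B 1
res$copy_matrix
#> Copy-number matrix (source A / source B); * marks discrepant cells
#>         species
#> enzyme   Cann Nsyl Ntab Slyc Smel Stub
#>   CHS    1/1  2/3* 3/2* 1/1  1/1  1/1
#>   CHI    0/1* 0/0  0/0  2/1* 3/2* 1/1
#>   F3H    1/1  1/1  1/1  1/1  1/1  1/0*
#>   F3pH   1/2* 1/1  1/1  1/1  1/1  1/1
#>   F3p5pH 2/2  1/1  1/1  1/2* 2/2  2/1*
#>   DFR    2/1* 1/1  1/1  1/1  1/1  1/1
#>   ANS    0/1* 1/1  1/1  0/0  2/2  0/0
compare_to_truth(res, sim)$fraction
#> [1] 1
```

Reading the report: of the 47 source-A and 46 source-B homologs, 41
loci are shared (34 with byte-identical CDS, 7 with boundary or
sequence differences), a handful are unpaired on either side, and four
redundant duplicates were excluded — and `34 + 7 + 3 + 3 = 47` adds up,
as it must.  Here the pipeline reproduces the simulator's implied
category for every gene (`fraction = 1`).

Real annotations are analysed the same way: build the two annotation
sets with `parse_annotation_set()` (FASTA plus an optional GFF3 or
two-column locus map), supply enzyme seed CDS named `CHS`, `CHI`, …,
and call `concordance_analysis()`.  A staged on-disk variant with
manifests is available via `pipeline_config()`/`run_stage()` (stages
`simulate`, `normalize`, `mine`, `classify`, `tree`, `rescue`,
`report`, `all`) and a thin CLI wrapper in `inst/cli/fbpconcord.R`.

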