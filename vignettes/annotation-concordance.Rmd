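---
title: "Assessing annotation concordance for anthocyanin biosynthesis gene families"
author: "fbpconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing annotation concordance for anthocyanin biosynthesis gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbpconcord)
```

## The problem

Gene copy number estimates depend on annotation quality.  When the same
genome has been annotated twice — for instance once by a unified
pipeline such as NCBI's eukaryotic annotation pipeline ("source A" here)
and once by a genome-specific project pipeline ("source B") — the two
coding-sequence sets for a gene family rarely agree exactly.  For the
seven core enzymes of the anthocyanin branch of the flavonoid
biosynthesis pathway (CHS, CHI, F3H, F3'H, F3'5'H, DFR, ANS), this
package quantifies that disagreement.  Each annotated homolog is
classified relative to the other source as:

* a **perfect pair** — reciprocal best hits whose coding sequences are
  identical strings;
* an **imperfect pair** — reciprocal best hits that differ in sequence
  and/or length;
* **unpaired** — no reciprocal partner; an unpaired annotation whose CDS
  is identical to another gene of the same source and species is
  discarded as redundant.

Unpaired genes from different sources that are sisters in a gene tree
are reclassified as imperfect pairs (they are very likely the same locus
annotated with diverged coordinates), and the surviving records feed
copy-number and length summaries per enzyme and species.

## Pipeline stages and their parameters

### Normalization

Each source is reduced to one candidate CDS per locus:

1. Sequences that may carry UTRs are replaced by their longest open
   reading frame (forward strand, all three frames, ATG to the first
   in-frame stop; an ORF reaching the sequence end without a stop is
   kept as an open 3' ORF).  ORFs shorter than **300 nt** are rejected —
   shorter fragments are rarely informative enzyme annotations and
   inflate spurious homolog counts.
2. Transcript variants are collapsed by keeping the longest sequence at
   each locus; equal lengths fall back to the lexicographically smallest
   transcript id so the choice is reproducible.  Sources that ship
   "primary transcript" sets pass through unchanged.
3. A CDS that is more than 10% ambiguous bases (N) is dropped: such
   records produce degenerate alignment columns downstream while adding
   no pairing information.

Locus identity comes from a feature table when one exists (GFF3
mRNA-to-gene links or a two-column id map); otherwise a trailing
`.<integer>` isoform suffix on the transcript id is stripped, which
matches the common convention of versioned transcript identifiers.

### Homolog mining

Candidate homologs are found by a relaxed local similarity search of
seed queries against each normalized source, with match +1, mismatch
-1, and an E-value ceiling of 1e-50.  The internal backend computes
optimal Smith–Waterman local alignments under that scheme (affine gaps,
open 5 / extend 2 — conventional companions of ±1 nucleotide scoring and
configurable) and converts scores to E-values with the Karlin–Altschul
form `E = K m n exp(-lambda S)`.  For ±1 scoring with uniform base
composition `lambda = log 3` exactly; `K` is fixed at 0.1.  Applying
ungapped statistics to gapped scores and freezing `K` is a deliberate
approximation: every decision the pipeline takes depends on
thresholding at very small E-values, where the threshold moves by only a
few score points per order of magnitude of `K`.  A gene hit by seeds of
several enzymes is assigned to the enzyme with the best bit score, with
ties broken in the fixed enzyme order; the cytochrome-P450 pair
F3'H/F3'5'H (CYP75) is additionally reported as one merged set because
the two enzymes share recent ancestry and are best read jointly.

### Pair classification

Reciprocal best hits are computed within each (species, enzyme) family,
never across families — cross-family pairing is precisely the paralogy
confusion the tree stage is designed to resolve.  "Best" is the highest
alignment score, then higher percent identity, then the smallest
partner id; determinism matters more here than any specific tie-break.
A pair is PERFECT if and only if the two CDS are identical strings.
This is the symmetric reading of "100% identity over 100% of the
length": a one-directional coverage test would let a perfect substring
count as perfect.  For imperfect pairs the local-alignment identity and
the length ratio (longer/shorter) are recorded.

### Gene trees and rescue

Per enzyme, all non-redundant members of both sources are aligned with
the package's codon-aware progressive aligner: a neighbor-joining guide
tree on 6-mer distances, then profile–profile global alignment whose
unit is the whole codon, so gaps always come in frame-preserving
triples.  Alignments are trimmed to conserved codon blocks: a codon
column survives when its gap fraction is at most `b5 = 0.5` and its
majority codon reaches `b2 = 0.5` of the non-gap rows, and surviving
runs must be at least `b4 = 5` codons long.  Trees are built by
neighbor-joining on pairwise GTR distances obtained in closed form from
each pair's symmetrised divergence matrix
(`d = -tr(Pi logm(Pi^{-1} F))`), with gamma rate heterogeneity (shape
1 by default) applied as the usual eigenvalue transform
`-log e -> alpha (e^{-1/alpha} - 1)`; this transform is exact for
equal-frequency models and an approximation under full GTR.  Supports
come from a nonparametric bootstrap over codon columns (1000 replicates
by default), resampled deterministically from the run seed.

A "unique cluster" of unpaired genes is operationalized as a
**cherry**: a two-leaf sister clade holding exactly one unpaired gene
from each source, from the same species.  This is the strictest reading
and minimizes false rescues; the cost is that a true pair separated by
an intervening leaf is left unpaired, which we consider the right
trade-off for a concordance audit.  Bootstrap support is not required
for a rescue by default (`min_support = 0`), but a minimum support can
be demanded.  Rescue never merges two leaves of the same source and
conserves the total gene count.

The final merged set keeps the source-A member of every pair — a single
consistent preference so cross-species sets are drawn from one
annotation style — plus all remaining unpaired genes.

### Summaries

Concordance totals obey the accounting identities
`totals_A = perfect + imperfect + unpaired_A + excluded_A` (and the B
analog) by construction, and the report re-checks them on every call.
Copy-number matrices are per (enzyme, species, source) with
discrepancy and zero flags and marginal sums.  Length statistics use
the population (n-denominator) standard deviation; with single-digit
strata the sample estimator's inflation is more misleading than the
population one's bias, and a singleton stratum then reports exactly 0.

## The synthetic data generator

Because real paired annotations cannot be bundled, the package ships a
generator that emulates their statistical structure with known ground
truth.  Gene families arise from a linear birth–death process along a
species tree (default: a 21-taxon eudicot-like topology with eight
Solanaceae, root-to-tip depth about 0.3 substitutions/site; duplication
rate 2 and loss rate 0.5 per branch-length unit, giving a realistic
mean of about 1.5 copies per species per family).  Sequences evolve
under K80 (kappa = 2 by default, JC as the special case) with codon
positions independent; the start codon and terminal stop are held
fixed and internal codons that mutate into stops are resampled, so
every true gene remains a well-formed CDS whose longest ORF is itself.

Each of the two emitted sources then corrupts the true genes
independently, reproducing the four discrepancy modes the analysis must
detect:

* **missed genes** (`miss_prob = 0.1`);
* **coding-boundary discrepancies**: transcripts gain UTR flanks
  (`utr_extend_prob = 0.3`); with probability `boundary_shift_prob =
  0.3` the 5' flank carries an in-frame upstream ATG fused stop-free to
  the true CDS, so the re-inferred CDS genuinely shifts — flanks are
  otherwise built ATG-free so ORF inference recovers the truth, which
  separates "annotation length discrepancy" from harmless UTR noise;
* **in-frame 3' truncations** (`truncation_prob = 0.05`, never below
  300 nt);
* **redundant transcript variants** (1–4 per locus) cut strictly into
  the CDS so the longest-variant rule must recover the representative,
  and **identical within-source duplicates** at fresh loci
  (`identical_duplicate_prob = 0.05`).

The truth table records, per true gene, its presence, representative
ids, the CDS each source should yield after ORF inference, and the
concordance category all of that implies.  The implied category is
computed from the corruption events alone (string comparison of the
expected CDS), not by running the analysis pipeline.

What the generator does **not** emulate: within-CDS indels, intron
structure and splice-variant biology, codon usage and selection,
base-composition heterogeneity, assembly errors, and cross-family
sequence similarity (seed families are drawn independently, so family
assignment is essentially noiseless compared with, e.g., the real CHS
superfamily).  Passing the end-to-end recovery checks therefore
demonstrates the bookkeeping and the classification logic, not
robustness to every failure mode of real annotations.

## Numerical choices and degenerate inputs

* All RNG-dependent steps (simulation, bootstrap) consume an explicit
  seed; reruns are byte-identical.
* Saturated or degenerate sequence pairs (no shared sites, vanishing
  eigenvalues) are capped at distance 10 substitutions/site rather than
  returning infinities; identical rows short-circuit to exactly 0.
* Negative NJ branch lengths are clamped to 0.
* Rows that are fully gapped after trimming are excluded from the tree
  with a warning; their pair records are untouched.  If trimming
  removes every column the pipeline falls back to the untrimmed
  alignment (again with a warning), since an unfiltered tree is more
  useful than none for rescue.
* Alignment input order never changes the result: sequences are
  canonically sorted before guide-tree construction.

## Validation problem sizes

The shipped tests and the acceptance script exercise: a corruption-free
10-species, 7-family run (exact recovery required); 20 corrupted
replicates for the accounting identities; about 1000–1700 pooled true
genes at default corruption for category recovery (bootstrap supports
disabled there, as rescue does not require them); 20 planted
cross-source boundary-shifted pairs for rescue; 30 random pairs up to
200 nt against an independent optimal-alignment oracle; 5-taxon
topology recovery; and 2000 birth-process replicates plus a
2001-site JC branch for simulator calibration.

## Known limitations

* The tree backend is distance-based (NJ on GTR distances); it stands
  in for full maximum-likelihood search, which is out of scope.  For
  rescue decisions only the local cherry structure matters, where NJ on
  near-additive distances is reliable.
* The E-value calibration is approximate (see above); absolute E-values
  should not be compared against other search engines, only the
  thresholding behaviour.
* RBH classification inside one enzyme family cannot detect a homolog
  mis-assigned between families; with strongly divergent seed families
  this is negligible, but closely related subfamilies (CHS-like
  proteins) blur the boundary in real data.
* The cherry rescue rule is conservative by design; a config widening
  to larger single-unpaired-per-source clades is a possible extension
  and deliberately not the default.
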