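---
title: "Methods: miRNA-target network hubs, homology, relative quantification and enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA-target network hubs, homology, relative quantification and enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirhub)
```

mirhub implements a complete in-silico-to-validation workflow around a
panel of regulated microRNAs: integrate target predictions from several
databases, rank predicted mRNA targets by how many panel miRNAs converge on
them, translate the panel to a second species by sequence homology, test
tissue expression by relative qPCR quantification, and summarize the target
list functionally by overrepresentation analysis. This vignette describes
each model, its assumptions, the tunable parameters, and the design
decisions taken where the workflow's conventions are genuinely open.

## The interaction network and its hub statistic

Predicted miRNA-target interactions arrive as tab-delimited tables in three
dialects, mirroring the ecosystem's main resource types: score-based
predictions on a 0-100 confidence scale (miRDB-like), score-based
predictions on a non-positive regression scale where more negative is
stronger (mirSVR-like), and manually curated experimentally validated
interactions without scores. Inclusion is by *strict* thresholds - score
> 80.0 for the first dialect and score < -1.2 for the second (both
configurable via `filter_thresholds()`); boundary scores are excluded.
Validated records always pass, reflecting their different evidence class.

The kept records define a bipartite graph: miRNA nodes (keyed
species-agnostically, so `rno-miR-139-5p` and `ssc-miR-139-5p` are one
node) and gene nodes, with one edge per distinct (miRNA, gene) pair and the
union of supporting databases attached as edge evidence. The single
centrality used is the **node degree** of a gene: its number of distinct
miRNA partners. Evidence multiplicity deliberately does not inflate degree
- a pair reported by all three databases still counts once, because degree
is meant to measure regulatory convergence of the panel, not annotation
redundancy. Genes are ranked by descending degree; ties are broken
alphabetically purely for determinism, since no biological ordering exists
within a degree class. Genes at or above `min_degree` (default 3) are
called target hubs. `extract_neighborhood()` induces the subnetwork of the
hubs and their adjacent miRNAs; whether the *other* targets of those
miRNAs (the second shell) belong to the neighborhood is a presentation
choice with no downstream effect, so both behaviors are available via
`include_cotargets`.

Two open conventions are worth recording. Multiple score rows for one
(miRNA, gene) pair within one database are all thresholded row by row;
optionally (`strongest_site_only`) mirSVR-like records can first be reduced
to their strongest (minimum) score per pair, for inputs that list one row
per predicted binding site. And the order of panel restriction versus
database union is immaterial - both operations commute - so the pipeline
applies the panel restriction first only to keep logged row counts small.

## Cross-species homology

Mature miRNAs are about 22 nt, so heuristic database search adds nothing
over the exact answer: `global_align()` runs full Needleman-Wunsch dynamic
programming with match +1, mismatch 0, gap -1 and a deterministic traceback
(diagonal preferred, then the gap consuming a query base, then a subject
gap). Percent identity is identical columns over the *alignment length*
(gap columns included). Because the field also quotes identities relative
to the shorter sequence - and the two conventions genuinely disagree for
gapped alignments of unequal-length miRNAs - the shortest-sequence
denominator is provided as an option (`identity_shortest`,
`percent_identity(..., denominator = "shortest")`); neither is asserted to
be the "right" one.

The **seed** is taken as nucleotides 2-8 (a 7-mer, 1-based inclusive).
Published seed conventions vary between 2-7 and 2-8; the 2-8 window covers
both for the purpose of calling two seeds identical, and the bounds are
arguments (`seed_start`, `seed_end`) for users who prefer the 6-mer.
`match_homologues()` reports, per query, the subject with maximal identity
(alphabetical tie-break) plus a `seed_identical` flag - the biologically
meaningful signal when full-sequence identity is low, since seed identity
is what preserves target repertoires across species.

DNA-alphabet input (`T`) is silently normalized to `U`, because public
mature-miRNA FASTA files mix both conventions; any other character is an
error, not a warning.

## Relative quantification and group testing

qPCR crossing points (Cp) are modeled long-format over samples x assays
with a declared housekeeping assay and reference group. Per sample,
`delta_cp = cp_target - cp_housekeeping`; per group,
`delta_delta_cp = delta_cp - mean(delta_cp of the reference group)`; the
per-sample fold change is exactly `2^-delta_delta_cp`, so
`log2(fold) = -ddCp` with no approximation and the reference group's fold
computed from its own mean dCp is identically 1. Amplification-efficiency
correction is out of scope: the plain base-2 rule is the method being
provided. Samples missing the target assay are dropped with a warning
rather than imputed - unequal group sizes (4-6 here) are the norm when
tissue availability varies. The per-group summary is the arithmetic mean
of per-sample folds (matching how individual points are usually plotted);
a geometric mean is also reported, and it is the better choice when folds
are analyzed on the log scale.

Group comparison is one-way ANOVA (delegated to `stats::lm`/`anova`)
followed by **Dunnett's many-to-one test**: each treatment group versus the
single reference, t statistics on the pooled within-group variance with
N - k degrees of freedom, familywise adjustment under the multivariate t
with the Dunnett correlation structure
(lambda_i = sqrt(n_i / (n_i + n_0))). Two evaluation routes are provided:
`"montecarlo"` (default), which samples the null max-|t| distribution with
10^5 draws under a fixed seed (default 1), and `"mvt"`, which evaluates the
rectangle probability by `mvtnorm::pmvt` quasi-quadrature. Both are
deterministic given the seed; the Monte Carlo default makes the adjustment
self-contained and its error easy to reason about (~3 x 10^-3 at p ~ 0.05),
while `"mvt"` is faster inside simulation loops and is what the
familywise-error simulation in the test suite uses. With one comparison
group the adjusted p is set exactly equal to the unadjusted pooled t-test
p. Adjusted p-values are clamped to be at least the unadjusted p, so the
adjustment can never be anti-conservative through numerical noise. Whether
to run the ANOVA on fold changes or on ddCp values is not standardized in
the field; the pipeline defaults to fold changes and the functions accept
either, since the user controls the vectors passed in.

## Overrepresentation

For a study set of n genes against a background of N, a term annotating K
background genes with k study hits gets the upper-tail hypergeometric
probability P(X >= k) (`stats::phyper`), expected count nK/N, fold
enrichment k/(nK/N), and a Bonferroni-corrected p with multiplier equal to
the number of terms actually tested (k >= 1). That multiplier choice is
documented rather than canonical - correcting over all terms in the map is
the conservative alternative and differs only by the number of untested
(k = 0) terms. The annotation map is flat: no ontology-graph propagation,
no term-redundancy reduction, no FDR - the method here is the classical
exact test with Bonferroni, and `top_terms()` reports the m = 25
highest-fold-enrichment significant terms by default. The background
defaults to all genes in the map unless supplied explicitly.

## The synthetic-data generators

All four generators are pure functions of their arguments and one integer
seed; substreams are split by a fixed multiplier rule so that the same seed
drives independent streams per generator, and the caller's RNG state is
never touched. The defaults encode the study conditions this workflow was
built around:

- `simulate_interaction_tables()`: an 18-miRNA panel, a planted hub gene
  receiving exactly k = 5 above-threshold interactions from distinct
  miRNAs, background edges at probability 0.02 per (miRNA, gene) pair, and
  40% of background records drawn *below* the inclusion thresholds so that
  filtering is genuinely exercised. Surviving background degree is capped
  at k - 1 per gene, making the planted hub the unique top-degree gene by
  construction - the generator defines the recovery benchmark, so recovery
  failures indicate pipeline defects, not generator chance.
- `simulate_profile_interactions()`: realizes an exact degree profile; the
  default profile is the published scale of the network this package
  models - 882 target genes of 18 miRNAs with one gene at degree 5, 14 at
  degree 3 and 69 at degree 2 (hence 84 multi-targeted genes and 15 hubs at
  cutoff 3) - plus 200 sub-threshold noise rows.
- `simulate_mirna_fasta_pair()`: 4 fully conserved rat/pig pairs and 1
  pair sharing only the seed, with non-seed positions mutated at
  probability 0.5; intended identities in the truth table are computed with
  the package's own public identity definition, so generator and analysis
  cannot drift apart silently.
- `simulate_cp_table()`: groups Isch (reference, n = 6), IPreC (n = 4),
  IPostC (n = 6); housekeeping Cp ~ Normal(20, sd), target Cp =
  housekeeping + baseline dCp (5 cycles) - planted log2 fold +
  Normal(0, sd), with sd = 0.3 cycles by default - a realistic
  technical-plus-biological spread for tissue qPCR. In the noiseless limit
  the planted folds are recovered exactly.
- `simulate_annotation()`: 50 terms of sizes 20-60 over a background of
  2000, one term of size 40 planted at 5x its expected study-gene count.

What the generators do *not* emulate matters for interpreting green tests:
real prediction databases have correlated scores across databases and
non-uniform score distributions; real miRNA families evolve with indels and
arm switching, not i.i.d. point mutations; real Cp noise has outliers and
plate effects; real GO annotations are hierarchical and strongly
overlapping. Passing the planted-structure benchmarks therefore
demonstrates correctness of the computations, not robustness to every
pathology of real data.

## Numerical choices and degenerate inputs

Problem sizes were chosen so the full suite runs in well under a minute of
CPU: alignment oracles enumerate sequences up to length 8, hypergeometric
enumeration runs at N <= 12, the familywise-error simulation uses 2000
replicates of the 6/4/6 design, and recovery checks use 20 generator
seeds. Empty record sets flow through filtering and network construction
as empty results; an empty network yields an empty ranking; zero-variance
expression input makes the ANOVA F degenerate (the underlying `stats`
machinery warns), which is surfaced rather than masked. Errors name the
offending entity - the missing column, the sample without housekeeping, the
unknown hub symbol - because these tables are edited by hand in practice.

## Known limitations

Degree is the only centrality; no betweenness or module detection.
Alignment is global-only, appropriate for mature miRNAs but not for
precursor or genomic sequences. The Dunnett implementation assumes
variance homogeneity across groups (the classical pooled test). Enrichment
treats terms independently, as Bonferroni does. The pipeline's paper-scale
claims rest on the profile generator, not on the original databases, which
are not redistributable.
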