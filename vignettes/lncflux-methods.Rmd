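---
title: "lncflux: models, definitions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncflux: models, definitions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncflux)
```

# Scope

lncflux packages the post-alignment analysis layers of a scheduled
high-intake feeding transcriptome study in waterfowl: lncRNA discovery
from assembled candidate transcripts, positional classification against
protein-coding genes, differential-expression and variance-component
summaries, correlation-based lncRNA function prediction, ortholog family
categorization with gene-set enrichment, and the feeding-schedule energy
model. Read alignment, transcript assembly, database-backed coding
potential classifiers and online GO/KEGG enrichment services are out of
scope; the package consumes their outputs (GTF files, FPKM tables, score
tables, family membership tables) instead.

This vignette records the models, the exact definitions behind each
decision rule, and why the open design choices were resolved the way they
were. Every number shown here is computed by the package at build time.

# The discovery cascade

Candidates pass four filters in a fixed order, and each removed
transcript is attributed to the *first* failing stage so the report's
counts always account for every input:

1. **Class code.** A candidate whose structural relation to the
   reference annotation is `=` (same strand, exonic overlap, identical
   intron chain — terminal exon ends may differ) or `c` (same strand,
   exons contained in a reference transcript's exonic union, every
   candidate intron exactly matching a reference intron) duplicates a
   known transcript and is removed. The remaining context codes are `o`
   (other same-strand exonic overlap), `x` (opposite-strand exonic
   overlap only) and `u` (no exonic overlap); they are recorded but not
   filtered on. Only the codes the cascade acts on are implemented; the
   full assembler-comparison taxonomy is not reproduced. Candidates with
   unknown strand (`.`) cannot be compared strand-wise and are removed at
   this stage under their own counter.
2. **Length.** Spliced (summed-exon) length below 200 bp. Spliced
   length, not genomic span, is the conventional lncRNA length
   definition and is what a minimum-transcript-length rule means for a
   spliced transcript.
3. **Coding potential.** Score above 1 is removed. The built-in score is
   deliberately simple and deterministic: the longest open reading frame
   across the three forward frames (ATG through the last sense codon;
   an ORF still open at the sequence end counts), in codons, divided by
   100 — so the "score > 1" convention corresponds to an ORF longer than
   100 codons. Database-backed classifiers (SVM scores against a protein
   database, covariance-model scans) are not reproducible at desk scale;
   externally computed score tables are the fidelity path and override
   the heuristic per transcript id (duplicates resolve last-wins with a
   warning). Scores are only evaluated for candidates that survive the
   earlier stages; a candidate reaching this stage with neither a
   sequence nor an external score is an error naming the transcript.
4. **Exon count.** Mono-exonic transcripts are removed (assembly
   artifacts and fragments dominate that class).

# Positional categories

Distances are measured between genomic spans: the gap is the number of
bases strictly between the two spans (0 for overlapping or abutting),
and the signed distance follows the *gene's* strand — negative when the
lncRNA lies downstream of the gene's 3′ end, positive when upstream of
its 5′ end. The nearest gene minimizes the gap, with ties broken by the
lexicographically smaller gene id. Coordinates are 1-based and closed
throughout (the GTF convention).

The five-category taxonomy is defined geometrically:

* same strand, overlapping → **sense genic**;
* same strand, non-overlapping → **sense intergenic**;
* opposite strand, non-overlapping, gap at most the orientation window
  (default 10 kb): 3′ ends facing → **convergent**, 5′ ends facing →
  **divergent**;
* opposite strand, gap beyond the window → **antisense intergenic**.

Two points deserve justification. First, for two non-overlapping
transcripts on opposite strands the facing ends are *always* either
3′–3′ or 5′–5′ — a "tandem" (5′-facing-3′) arrangement requires equal
strands — so a taxonomy that wants a distinct opposite-strand intergenic
class must separate it by distance, not by a third orientation. The
orientation window (defaulting to the same 10 kb used for cis
candidates) does this: nearby opposite-strand lncRNAs are convergent or
divergent — categories whose regulatory interpretation rests on the
shared promoter region or 3′-end overlap, both proximity phenomena —
while distant ones are plain antisense intergenic. This is also the
reading consistent with a convergent lncRNA being a special case of an
intergenic antisense lncRNA a few kb downstream of its gene. Second,
the taxonomy has no "antisense genic" class, so an opposite-strand
lncRNA that *overlaps* its nearest gene is assigned by the same
orientation logic evaluated on the relative positions of the two
midpoints (ties resolve toward the 3′ side), with the overlap flagged in
the record. This keeps the five categories a total partition.

Cis-candidate annotation is separate from classification: *all*
(lncRNA, gene) pairs with gap ≤ 10 kb are reported (window boundary
inclusive), not only nearest-gene pairs, and the nearest gene is
additionally recorded per lncRNA. Span-to-span distance is used rather
than TSS-to-TSS: a 10 kb rule phrased as "upstream or downstream of a
gene" most naturally bounds the gap between the transcribed regions, and
span distance is monotone under the exon structures involved.

# Expression statistics

**Expressed features.** A feature is expressed when its maximum FPKM
across the relevant samples strictly exceeds 0.1. The maximum is the
most permissive deterministic aggregation consistent with a "FPKM > 0.1"
phrasing; the mean is available by argument.

**Differential expression.** Per tissue, Welch's two-sample t-test on
log2(FPKM + 1) between treatments, Benjamini–Hochberg q-values across
features, and `is_de` = q < 0.05 (configurable). This is a documented
stand-in for assembler-integrated DE engines that model read-level
abundance uncertainty; those operate on inputs unavailable at desk
scale, and everything downstream consumes only the DE calls. Numerical
conventions: fold change is `(mean_treated + 1e-6)/(mean_control + 1e-6)`
on the FPKM scale (the pseudo-abundance keeps zero-mean groups finite); a
feature with zero variance in both groups has p = 1 when the means are
equal (no evidence) and p = 0 otherwise (infinite standardized
difference); DE percentages are rounded half-up to two decimals, the
convention of printed percentages, not banker's rounding.

**PVCA.** Features are standardized across samples; principal components
of the samples are extracted; each retained PC's scores are decomposed by
the balanced two-way crossed random-effects expected-mean-square
equations (method of moments via the ANOVA mean squares): with `a`
tissues, `b` treatments and `n` replicates,

σ²(interaction) = (MS_AB − MS_E)/n, σ²(tissue) = (MS_A − MS_AB)/(bn),
σ²(treatment) = (MS_B − MS_AB)/(an), σ²(residual) = MS_E.

The per-PC components are pooled with eigenvalue-share weights *before*
truncating negatives and normalizing. The ordering matters: truncating
each PC separately inflates the factor shares, because with 18 samples
each PC's moment estimates are noisy and the truncation keeps only their
positive excursions — a bias that no number of features removes. Pooling
first lets opposite-signed fluctuations cancel. By default the full
eigenvalue spectrum is retained, which makes the pooled decomposition
exactly the sums-of-squares decomposition of the standardized data
(rotation invariance) and therefore well calibrated: pure noise yields a
residual share near 1, and tissue-only signal yields a tissue share of
exactly 1 (both are asserted in the test suite). Retaining fewer PCs
(`n_pcs` or `min_var_explained`) denoises at the cost of upward bias in
the factor shares and is available as an option rather than the default.
Unbalanced designs are rejected by the ANOVA estimator with a pointer to
the group-means fallback (`method = "means"`), which estimates the same
four components from tissue/treatment/cell means and within-cell
variances.

# Co-expression pairs

Pearson correlation on log2(FPKM + 1) across all shared samples (the
pooled 18-sample design by default), with the classical two-sided
p-value from `t = r·sqrt((n − 2)/(1 − r²))` on n − 2 degrees of freedom.
Pairs are retained at **signed** r > 0.80 (anti-correlated pairs are
excluded; an absolute-value variant is a flag) and raw p < 0.05 — no
multiple-testing correction, since the thresholded-r rule is the
published convention for this analysis; BH adjustment across pairs is
available by flag. Both thresholds are strict inequalities, so r = 0.80
exactly is excluded. The cis join intersects correlated pairs with the
10 kb proximity pairs and ranks by descending r, ties by smaller
absolute distance, then lexicographic ids.

Note that across a pooled multi-tissue design, strong tissue effects
alone produce many high correlations between features — the correlation
captures co-variation over tissues as much as co-regulation within them.
That is inherent to the pooled design, not an artifact; a per-tissue
option exists for the narrower question.

# Ortholog families and enrichment

Families are categorized purely from the (focal, reference) copy-count
pair: (1,1) one-to-one; focal > reference (both ≥ 1) expansion; focal <
reference contraction; equal multi-copy counts many-to-many; a zero on
one side makes the family species-specific (split into focal-specific
and reference-specific for auditability). Category proportions are
reported over families containing the focal species. Longest-CDS
selection keeps one transcript per gene (ties to the lexicographically
smaller transcript id) and drops peptides shorter than 50 amino acids —
a strict "fewer than 50" rule, so 50 aa survives. Sequence-similarity
clustering itself (BLAST, hierarchical clustering, alignment ranking) is
out of scope; the module consumes a family membership table.

Gene-set enrichment among DE genes uses Pearson's chi-square on the 2×2
membership table over an explicit universe — the universe is a required
input because the appropriate background (all expressed genes vs all
orthologs) is a study-level decision, not something the statistic should
guess. No Yates correction by default (the correction is conservative
for the large tables this is meant for, and both variants are exposed);
the odds ratio applies a 0.5 continuity adjustment only when a zero cell
exists, flagged in the result; an expected cell below 5 triggers a
warning recommending an exact test.

# The feeding-energy model

Meal size grows linearly per calendar day — `base + increment·(day − 1)`
grams — and the number of meals per day is piecewise constant over
contiguous phases covering days 1..N. The packaged default is the 18-day
fattening schedule (130 g on day 1, +5 g/day; 2 meals/day on days 1–3,
3 on days 4–6, 4 on days 7–17, 3 on day 18; 14.29 MJ/kg metabolizable
energy) against an ad libitum control of 325 g/day over the same 18 days
(the last day is included symmetrically for both groups; the overnight
feed deprivation before sacrifice cancels out of the difference).
The per-day increment (rather than per-meal) is the interpretation under
which the packaged schedule reproduces the published 72.81 MJ energy
difference, and is therefore fixed:

```{r energy}
total_intake(goose_fattening_schedule())          # grams over 18 days
energy_difference(goose_fattening_schedule(), goose_control_intake())
```

Control energy anchors on grams × energy density; at the packaged values
this coincides with the quoted per-day energy level. Total intake is
implemented twice — an arithmetic-series closed form and a day loop —
and the two must agree exactly (a standing cross-check in the tests).

# The synthetic-data generator

The generator emulates the study's *structure*, not its sequences: 3
tissues × 2 treatments × 3 biological replicates = 18 samples, FPKM-like
values, a toy multi-chromosome genome. Its defaults are the package's
statement of the study conditions:

* **Geometry.** Two-exon protein-coding genes on fixed-width slots with
  at least 25 kb between gene spans, so the 10 kb cis window is
  unambiguous and every planted lncRNA's nearest gene is its anchor by
  construction. LncRNAs are placed by explicit geometry per category
  (genic ones inside the anchor's intron; convergent/divergent at
  2–8 kb on the appropriate flank; antisense intergenic at 12–18 kb,
  beyond the orientation window). Decoy candidates engineered to fail
  each cascade stage (a reference copy with extended terminal exons, a
  contained mono-exon, a 170 bp transcript, a transcript carrying a
  150-codon ORF, a benign mono-exon) are planted alongside.
* **Expression.** Per feature, log2 FPKM = baseline (normal, mean 3,
  sd 1.5) + per-tissue effect (sd 1) + treatment effect ± de_log2fc on
  the planted DE genes of each tissue (sign randomized) + N(0, noise_sd)
  replicate noise; FPKM = 2^log2x, hence non-negative and log-normal.
  Planted lncRNA–mRNA pairs share a per-sample Gaussian latent factor
  with loading `noise_sd·sqrt(r/(1 − r))`, which gives expected Pearson
  correlation exactly r between the pair members; pair members carry no
  tissue or treatment effects so the planted correlation is
  unconfounded.
* **Noise level.** The default replicate noise is sd 0.25 on the log2
  scale (≈ 18% CV) — the low-noise regime of a controlled, single-breed,
  same-age feeding experiment, and the regime in which a planted
  log2FC = 3 effect at n = 3 vs 3 is recoverable by design. This is the
  condition under which the recovery guarantees (DE sensitivity ≥ 0.9 at
  observed FDR ≤ 0.1) are stated; at field-realistic noise (sd ≥ 0.5,
  ≈ 40% CV) Welch tests at n = 3 lose half their sensitivity, which is a
  property of the design, not of the implementation.
* **Families.** Long-format tables realizing the planted category mix
  exactly (rounded per category, remainder to one-to-one), with focal
  gene ids drawn from the same id scheme as the expression features so
  the tables join.
* **Determinism.** A fixed config yields byte-identical output files;
  the three sub-generators use fixed offsets from the config seed so
  annotation, expression and family tables can be regenerated
  independently.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: library-size and
gene-length biases in FPKM, overdispersed count noise, correlated gene
programs beyond the planted pairs, assembly fragmentation, unannotated
reference genes, and sequence-level realism beyond what the ORF
heuristic needs. The recovery results are statements about the planted
regime, not field performance.

# Problem sizes and numerical conventions

The test suite and the acceptance script use these sizes, chosen to make
every stochastic check decisive at comfortable margins: 300 genes and 30
planted lncRNAs (6 per category) in the default fixture; 1000 randomized
placements for classifier–oracle equivalence; 200 regenerated expression
replicates (600 pair observations) for correlated-pair retention; 2000
features for the null PVCA calibration; 1000 random candidate/reference
structures for the class-code oracle. Statistical oracles (BH step-up,
explicit-sum Pearson with t CDF, expected-count chi-square) are compared
at 1e-10 relative tolerance. Ties everywhere resolve lexicographically
(nearest-gene ties, CDS-length ties, pair-rank ties after |distance|),
rounding of printed percentages is half-up at two decimals, and all
window boundaries (10 kb cis, 200 bp length, score 1, 50 aa) follow the
strict/inclusive conventions stated in their function documentation.

# Known limitations

* The class-code assigner implements only the codes the cascade acts on
  plus minimal context codes; it is not a general assembler-comparison
  tool.
* The DE stand-in ignores abundance-estimation uncertainty and count
  overdispersion; with n = 3 it is honest but weak at realistic noise.
* The built-in coding score is an ORF-length heuristic; real coding
  potential assessment should come through the external score table.
* PVCA assumes a balanced crossed design for its exact estimator; the
  means fallback for unbalanced data is approximate.
* Correlation-based pair prediction over pooled tissues conflates
  tissue-level and within-tissue co-variation (see above).
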