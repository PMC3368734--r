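---
title: "Methods: multi-tissue enrichment, splicing and TAR discovery"
author: "placentome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-tissue enrichment, splicing and TAR discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placentome)
```

# Overview

`placentome` re-implements, as a reusable and fully tested pipeline, the
classic bulk RNA-Seq analysis of a small panel of *target* tissues (the
motivating case is the three placental compartments: amnion, chorion and
decidua) against a larger *background* panel (a 16-tissue whole-body
reference). Four analyses share one data model:

1. gene-level FPKM quantification with tissue-enriched and
   tissue-specific gene calling;
2. junction-count based exon-inclusion (PSI) estimation with a Bayesian
   differential-splicing test;
3. Fisher's exact overlap enrichment of gene sets against external
   annotation lists;
4. clustering of reconstructed transcripts into transcriptional active
   regions (TARs) with novelty classification of TARs and their internal
   exons.

Raw sequencing data are deliberately out of scope: the package consumes
the standard summaries (annotation GTF/BED12, fragment-count and
junction-count tables, reconstructed transcript sets) and ships a seeded
synthetic-cohort generator with planted ground truth, so that every stage
is testable end to end without external data.

# Expression: FPKM and the enrichment callers

Gene expression is quantified as Fragments Per Kilobase of exon-union
length per Million mapped fragments:

$$\mathrm{FPKM}_{g,t} = \frac{C_{g,t}}{(L_g/10^3)\,(N_t/10^6)}$$

where $C_{g,t}$ is the fragment count of gene $g$ in tissue $t$, $N_t$
the tissue's total mapped fragments, and $L_g$ the number of genomic
bases covered by at least one exon of any isoform ("exon union"
counting). The union sidesteps the read-assignment ambiguity of
isoform-level estimation; the package does not attempt isoform abundance
at all.

Two callers classify genes against a background panel:

* **Tissue-enriched** (`callTissueEnriched`): target FPKM at least
  `minFpkm` (default 1) *and* strictly more than `minFold` (default 4)
  times the arithmetic mean of the background FPKM. The strict
  inequality is a deliberate choice — the usual informal phrasing
  ("greater than 4-fold") alternates with "at least"; we fix strict `>`
  and expose the threshold. A gene at exactly 4-fold is therefore not
  called. When the background mean is zero the fold is reported as
  `Inf` (no pseudocount), so a strongly expressed gene with an empty
  background passes any finite threshold; this keeps the enriched set a
  superset of the specific-and-well-expressed genes, and the caller
  reports both flags rather than forcing exclusivity.
* **Tissue-specific** (`callTissueSpecific`): a presence/absence rule on
  raw counts — not a single fragment in any background tissue, at least
  one in the target. A second flag marks specific genes whose target
  FPKM strictly exceeds 0.3, removing genes with universally low
  expression that were sampled in the target by chance; the two-stage
  reporting mirrors how such gene lists are usually published (a raw
  list, then a filtered one).

`selectDivergentGenes` reproduces the usual heat-map pre-selection: keep
genes with FPKM strictly above 5 in at least 8 tissues, rank by the
coefficient of variation of FPKM across all tissues (population standard
deviation by default; a switch gives the sample version), break ties by
gene id, keep the top 1,000. `clusterProfiles` performs unweighted
average-linkage (UPGMA) hierarchical clustering with the
$1 - \mathrm{Pearson}$ distance for both genes and tissues; the per-gene
z-score it returns is for display only and never enters the distances.
The pipeline correlates tissues on $\log_2(\mathrm{FPKM}+1)$: raw-scale
Pearson correlation is dominated by a handful of extreme FPKM values,
and log-scale correlation is the field's standard for expression trees.

# Splicing: PSI and the differential test

For a cassette exon with upstream-junction, downstream-junction and
skipping-junction read counts (UJC, DJC, SJC), the inclusion support is
$I = (UJC + DJC)/2$ — each included transcript copy offers two inclusion
junctions but only one skipping junction, so averaging puts the two
isoforms on the same per-transcript scale — and the inclusion level is

$$\Psi = \frac{I}{I + S}, \qquad S = SJC,$$

reported as missing (never zero) when $I + S = 0$. Comparisons between a
tissue and a pooled panel and between two tissues share one code path:
pooling is an element-wise sum of the three counts (`poolConditions`)
executed before estimation.

**Posterior probability.** `posteriorDiffProb` treats the two conditions
independently with uniform(0,1) priors on $(\Psi_1, \Psi_2)$ and a
binomial likelihood of $k = \mathrm{round}(I)$ successes in $k + S$
trials (round half-up; the alternative continuous "effective trials"
treatment was considered and rejected to keep a standard binomial
likelihood). The reported quantity is the posterior mass of
$|\Psi_1 - \Psi_2| > c$ with $c = 0.1$ by default (a ten-point inclusion
shift). With a single pooled sample per condition the multivariate prior
used by replicate-aware methods degenerates to independent uniforms,
which is what we implement. Integration is numerical on a grid
(`gridStep`, default 0.001): cell masses of the Beta posterior in one
coordinate, the exact Beta CDF in the other, symmetrised over the two
orderings so the function is exactly symmetric in its arguments. On two
empty conditions the result is the prior band-complement area
$1 - (2c - c^2)$ (0.81 at $c = 0.1$), which the tests pin to $10^{-3}$;
halving the grid step moves values by less than $10^{-3}$.

**p-value.** The frequentist companion is a parametric bootstrap under
the interval null $|\Psi_1 - \Psi_2| \le c$: fit the constrained
maximum-likelihood pair (a one-dimensional optimisation on the active
boundary when the unconstrained estimates are farther than $c$ apart),
simulate $B$ replicate count pairs at the observed informative totals,
and report $p = (1 + \#\{\text{replicate statistic} \ge
\text{observed}\})/(B + 1)$. The add-one correction keeps $p > 0$ and
the tie-inclusive comparison keeps the test valid. Because the truth
under an exact null ($\Psi_1 = \Psi_2$) lies strictly inside the
interval null, the p-values are conservative by construction; the test
suite therefore bounds only the anti-conservative excess of the p-value
ECDF. FDR adjustment is Benjamini–Hochberg. An exon is called
differential when the observed $|\hat\Psi_1 - \hat\Psi_2|$ exceeds $c$
and its FDR is below `fdrCutoff` (default 0.1); events with fewer than
`minInformative` (default 10) informative reads in either condition are
reported untested rather than silently dropped.

# Gene-set overlap

`buildOverlapTable` forms the 2×2 table of a query set against an
annotation list inside an explicit universe — the universe is never
inferred, because the right background (all annotated genes, expressed
genes, tested genes) differs between analyses. `fisherExact` computes
the hypergeometric tail conditioned on the margins; the default
alternative is "greater" (the enrichment question), the two-sided option
sums all tables whose point probability does not exceed the observed
one. The odds ratio is the sample odds ratio $ad/bc$ (with $\infty$ when
$bc = 0 < ad$), not the conditional-MLE estimate some implementations
report.

# TARs: clustering and novelty

Reconstructed transcript termini are unreliable, so single-exon records
are removed outright and all comparisons use **splice-site boundaries**:
every exon edge of a transcript except its outermost start and end
(2k − 2 coordinates for k exons). Boundaries are stored in the
between-base convention, so a donor and the next acceptor can never
collide numerically. Two transcripts overlap when they share a
chromosome, a strand and at least one boundary; TARs are the connected
components of this relation (so chains merge transitively), with ids
assigned in (chromosome, span start, strand) order for reproducibility.
A TAR is **novel** when no member shares a boundary with any annotated
transcript — span overlap with a known gene does not count. The
annotation side of the test also uses splice-site boundaries (termini
excluded), keeping the definition symmetric; multiple annotation sources
are concatenated and de-duplicated by exact exon-chain identity.

Internal exons of annotation-overlapping TARs fall into four exclusive,
exhaustive classes: *annotated* (exact coordinate match),
*one_end_shared* (start matches an annotated start or end matches an
annotated end), *overlap_no_shared_end*, and *no_overlap*. Edge sharing
is genomic (strand-aware but orientation-agnostic), since class
membership does not change under strand reflection. Novel-TAR expression
reuses `computeFPKM` and both callers with the union of member-transcript
exons as the gene model.

One ambiguity deserves record: whether a shared boundary must belong to
an internal exon *sensu stricto* (excluding the intron-facing edges of
terminal exons) cannot be settled from the usual informal definitions.
We implement the splice-site interpretation — terminal exons contribute
their intron-facing edge — because the stated reason for distrusting
termini applies to transcript ends, not to splice sites.

# The synthetic cohort

The generator (`simulateCohort` and the per-stage `generate*` functions)
emulates the study design rather than raw reads: 3 target + 16
background tissues, a few hundred genes, planted signal of every kind
the pipeline must detect. All stages are deterministic given the master
seed (each stage derives its own sub-seed, so stages rerun in isolation
reproducibly).

* **Annotation**: 4–9 exons per gene (150–350 bp, introns 300–800 bp),
  25 genes per synthetic chromosome with 8–15 kb intergenic gaps that
  leave room for planted intergenic transcripts. A seeded subset of
  genes carries a cassette exon.
* **Expression**: each gene has a log-normal base FPKM (median 8,
  ln-scale sd 1, floored at 0.8 so every background gene leaves a read
  footprint). Every tissue deviates from the base profile gene by gene
  (log-normal, `tissueLogSd = 1` on the natural-log scale — real tissues
  differ substantially), and the target tissues share a latent deviation
  factor (`targetCor = 0.5`), which is what makes the compartments of
  one organ cluster together, exactly as shared placental biology does.
  Planted enriched genes (10 per target plus 5 shared across all
  targets, mirroring the shared-compartment signature seen in real
  placental panels) are set in their target tissue to a fold drawn from
  5–50 times the gene's realised mean background FPKM, so the planted
  fold is the realised fold. Planted specific genes are structurally
  zero outside their target and expressed at FPKM 0.55–0.95 inside it:
  detectable, above the 0.3 reporting filter, and below the FPKM ≥ 1
  enrichment floor so the two planted classes stay disjoint. Counts are
  Poisson draws around the expected counts (a negative-binomial
  dispersion knob exists for stress tests; `dispersion = 0` switches to
  rounded expectations). Library sizes are the drawn per-tissue mapped
  totals (2–4 million): the modelled genes account for a small fraction
  of each library, as in a real experiment where most fragments fall
  outside any single analysis gene set.
* **Junctions**: per event and tissue, the informative total is
  Poisson(`junctionCoverageMean` = 100); $k \sim
  \mathrm{Bin}(n, \Psi_{\text{true}})$ inclusion events each yield one
  read on each inclusion junction, and the $2k$ inclusion reads split
  $\mathrm{Bin}(2k, 1/2)$ between UJC and DJC. UJC and DJC therefore
  differ (exercising the averaging) while their mean recovers $k$
  exactly, making $\hat\Psi = k/n$ unbiased given $n$. Null exons share
  one inclusion level everywhere; a fraction (10%) carries a planted
  shift of exactly 0.3 in every target tissue.
* **Reconstruction**: jittered copies of every annotated transcript
  (termini perturbed ±50 bp, splice sites intact), intergenic multi-exon
  plants (the novel TARs), copies of known genes with one extra intronic
  exon (the novel internal exons), and single-exon noise.

"Noise-free" in the recovery checks means all stochastic variation off:
`dispersion = 0` *and* `tissueLogSd = 0`. Under those conditions the
planted enriched and specific sets are recovered with sensitivity and
specificity 1 (enriched calls are compared net of specific calls, since
a specific gene with infinite fold is — intentionally — also
enrichment-positive). What the synthetic cohort does **not** emulate:
mappability and GC bias, fragment-length effects, alignment artifacts,
isoform mixtures beyond a single cassette exon, replicate structure, and
correlated noise between genes; passing tests show the statistics and
rules are implemented correctly at realistic magnitudes, not that the
pipeline is robust to every artifact of real libraries.

# Problem sizes and numerical choices

The test-suite and acceptance-script simulations use: 2,000 cassette
exons for the null-calibration and FDR-mixture checks (one target tissue
against the pooled 16-tissue background, bootstrap $B = 1000$); 50
random count pairs against a $10^6$-draw Beta Monte-Carlo oracle;
exhaustive PSI triples up to counts of 20; every 2×2 table with total up
to 30 plus the full slice at total 60 for Fisher's test; a 200-gene
noise-free cohort for recovery; and a 120-gene demo cohort for the
end-to-end reproducibility run. These sizes make the full suite run in a
few minutes on a single core while leaving the Monte-Carlo tolerances
comfortably above their standard errors.

Other numerical decisions: grid integration at `gridStep = 0.001`
(midpoint cells, exact CDF in the co-ordinate, symmetrised);
round-half-up for $I$; p-value ties counted in favour of the null;
BH step-up for FDR; CV ties broken by gene id; zero-variance rows and
columns dropped with a notice before correlation clustering (an
all-zero-variance matrix is an error); degenerate splice events (no
informative reads) reported as missing PSI and, in the test, as $p = 1$
with a notice.

# Limitations

The differential-splicing p-value is this package's own constrained-MLE
parametric bootstrap: the published analyses it follows defer their
p-value machinery to a replicate-aware MCMC method whose exact numbers
we make no attempt to reproduce. Absolute agreement with any particular
historical gene list is likewise out of scope — printed p-values from
the motivating studies depend on gene universes that are not
reconstructible from the publications. The callers implement the stated
thresholds faithfully; on real data their output is only as good as the
annotation and the library-size accounting fed to them.
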