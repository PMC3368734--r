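# placentome

Multi-tissue bulk RNA-Seq analysis of a small panel of target tissues
(the motivating case: the three placental compartments — amnion, chorion
and decidua) against a background tissue panel (a 16-tissue whole-body
reference). The package implements, as one tested pipeline with a shared
data model:

- **Expression**: exon-union FPKM quantification
  (`FPKM = C / (L/10^3) / (N/10^6)` with `L` the exon-union length),
  tissue-**enriched** calling (FPKM ≥ 1 and strictly > 4-fold over the
  mean background), tissue-**specific** calling (zero reads in every
  background tissue, with a secondary FPKM > 0.3 filter),
  divergent-gene selection by coefficient of variation, and
  average-linkage clustering on the 1 − Pearson distance.
- **Splicing**: cassette-exon inclusion levels from junction counts,
  `Ψ = I/(I+S)` with `I = (UJC + DJC)/2`, `S = SJC`; a Bayesian
  posterior probability `P(|Ψ1 − Ψ2| > 0.1)` under independent uniform
  priors and binomial likelihoods (grid integration); a constrained-MLE
  parametric-bootstrap p-value under the interval null `|Ψ1 − Ψ2| ≤ 0.1`;
  Benjamini–Hochberg FDR; calls at `|ΔΨ| > 0.1, FDR < 0.1`.
- **Gene-set overlap**: Fisher's exact test of a query set against an
  annotation list inside an explicit gene universe, with the sample odds
  ratio `ad/bc`.
- **Novel transcription**: clustering of reconstructed multi-exon
  transcripts into transcriptional active regions (TARs) by shared
  splice-site boundaries on one strand, novelty calls against a
  reference annotation, the four-way classification of internal exons
  (annotated / one end shared / overlap without shared end / no
  overlap), and FPKM-based enrichment flags for novel TARs.
- **Synthetic cohorts**: a seeded generator that plants enriched and
  specific genes, true inclusion levels with known shifts, novel TARs,
  novel internal exons and single-exon noise, so every stage has ground
  truth to recover. The full pipeline (`runPipeline`) runs
  synthesis → expression → splicing → overlap → TARs reproducibly from
  one seed.

The raw-sequencing side (alignment, transcript reconstruction) is out of
scope; the package consumes GTF/BED12 annotation and plain TSV count
tables, written and read by its own I/O layer.

## Worked example

```r
library(placentome)

cfg    <- CohortConfig(seed = 42L)        # 200 genes, 3 targets, 16 backgrounds
cohort <- simulateCohort(cfg)
te     <- computeFPKM(cohort$expression)
tn     <- tissueNames(cfg)

enr <- callTissueEnriched(te, "target_1", tn$background)
spc <- callTissueSpecific(te, "target_1", tn$background)
sum(enr$enriched)   # 29
sum(spc$specific)   # 5
head(as.data.frame(enr[enr$enriched, c(1, 3, 4, 5)]), 3)
#   gene_id targetFpkm backgroundMean     fold
# 1   g0014 147.857314       13.18925 11.21044
# 2   g0017 654.515934       17.39003 37.63741
# 3   g0025   1.172293        0.00000      Inf
```

The 29 enriched calls comprise the 15 planted enriched genes, the
planted specific genes that are also expressed above 1 FPKM (infinite
fold over an all-zero background, like `g0025` above), and genes whose
simulated biological tissue variation genuinely exceeds 4-fold — the
same mixture a real cohort produces.

```r
ds <- callDifferentialExons(cohort$events, "target_1", tn$background,
                            B = 1000, seed = 1)
unlist(ds$summary)
#         nEvents         nTested         nCalled    nGenesCalled pctTestedCalled
#              50              50               5               5              10
length(cohort$truth@shiftedExons)   # 5 -- exactly the planted shifts

tars <- classifyTarNovelty(clusterTars(filterMultiExon(cohort$reconstructed)),
                           cohort$annotation)
tars
# TarSet: 205 TARs from 210 multi-exon transcripts
#   novelty: 200 known, 5 novel
```

All 5 planted intergenic transcripts come back novel; all 200 jittered
copies of annotated transcripts come back known. `runPipeline()` chains
these stages, writes every table to disk, and returns a report whose
counts are recomputed from the outputs; identical config + seed gives
byte-identical files. A command-line wrapper with `synth`, `expression`,
`splice`, `overlap`, `tars` and `run` subcommands is installed at
`inst/scripts/placentome.R`.

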