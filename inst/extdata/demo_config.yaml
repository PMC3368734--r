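# demo cohort: small enough to run the full pipeline in a few minutes on
# one core, while exercising every stage
seed: 11
cohort:
  nGenes: 120
  nCassetteExons: 30
  nEnrichedPerTarget: 6
  nEnrichedShared: 3
  nSpecificPerTarget: 3
plant:
  nNovelTars: 4
  nNovelExons: 3
  nNoise: 6
  geneListSize: 20
  geneListOddsRatio: 10
analysis:
  bootstrapB: 300
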