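# 21-gene recurrence score, microarray approximation (unscaled).
# Sixteen target genes in four gene groups plus three singletons; the five
# RT-PCR housekeeper genes are omitted because input matrices are already
# between-array normalized. Group score = weighted mean of member genes
# (weights below; the ER group uses the published 0.8/1.2/1/1 weighting,
# the HER2 group 0.9/0.1). The proliferation group is floor-thresholded at
# the 80th percentile of ER-positive patients before combination.
name: rs21
targets:
  - {gene: BIRC5, group: proliferation, weight: 1.0}
  - {gene: MKI67, group: proliferation, weight: 1.0}
  - {gene: MYBL2, group: proliferation, weight: 1.0}
  - {gene: CCNB1, group: proliferation, weight: 1.0}
  - {gene: AURKA, group: proliferation, weight: 1.0}
  - {gene: ESR1, group: er, weight: 0.8}
  - {gene: PGR, group: er, weight: 1.2}
  - {gene: BCL2, group: er, weight: 1.0}
  - {gene: SCUBE2, group: er, weight: 1.0}
  - {gene: GRB7, group: her2, weight: 0.9}
  - {gene: ERBB2, group: her2, weight: 0.1}
  - {gene: CTSL2, group: invasion, weight: 1.0}
  - {gene: MMP11, group: invasion, weight: 1.0}
group_weights:
  proliferation: 1.04
  er: -0.34
  her2: 0.47
  invasion: 0.10
singleton_weights:
  CD68: 0.05
  GSTM1: -0.08
  BAG1: -0.07
threshold:
  group: proliferation
  percentile: 80
  reference: er_positive
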