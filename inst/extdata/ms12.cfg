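# 12-gene molecular score, microarray approximation.
# Eight target genes entering the score directly as a weighted sum.
# Proliferation-axis genes carry positive weights, ER-signaling-axis genes
# negative weights. Downstream per-cohort z-scoring makes results invariant
# to positive affine rescaling of these weights; the sign pattern and the
# relative magnitudes are what matters.
name: ms12
targets: []
group_weights: {}
singleton_weights:
  BIRC5: 0.31
  UBE2C: 0.08
  DHCR7: 0.06
  AZGP1: -0.07
  IL6ST: -0.14
  MGP: -0.04
  RBBP8: -0.09
  STC2: -0.31
threshold: null
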