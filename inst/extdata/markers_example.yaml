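# Example marker configuration for classifyCellTypes()/readMarkerConfig():
# cell type -> list of marker genes with normalized-expression thresholds.
astrocyte:
  - gene: Aqp4
    threshold: 1.0
  - gene: Gfap
    threshold: 0.8
oligodendrocyte:
  - gene: Sox10
    threshold: 1.0
  - gene: Olig1
    threshold: 1.0
microglia:
  - gene: Cd68
    threshold: 1.0
endothelial:
  - gene: Pecam1
    threshold: 1.0
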