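# Demo configuration: a full synthetic multi-region study at desk scale.
# Bulk arm: 27 regions x 2 conditions x 4 RNA replicates (216 transcriptomes)
# and 27 x 2 x 2 ChIP replicates over a consensus peak set; single-cell arm:
# 2 regions x 2 conditions x 5 replicates.
seed: 1
bulk:
  n_regions: 27
  n_genes: 2000
  n_replicates: 4
  n_modules: 8
  module_size: 25
  effect: 1.0
chip:
  rho: 0.8
  n_replicates: 2
scrna:
  n_types: 8
  n_genes: 1200
  cells_per_replicate: 120
  n_replicates: 5
  proportion_shift: {type: type03, region: dorDG, factor: 2}
  module_shift: {type: type01, region: dorDG, log2fc: 1}
  regulon_shift: {type: type02, region: dorDG, log2fc: 1, regulon: regulon01}
  lr_shift: {sender: type04, region: dorDG, log2fc: 1.5, pair: 1}
thresholds:
  q_bulk: 0.1
  q_pseudobulk: 0.2
  q_regulon: 0.1
  alpha_proportion: 0.05
modules:
  k: 8
  n_restarts: 25
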