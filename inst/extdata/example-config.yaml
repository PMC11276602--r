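# Example pipeline configuration for the cuporigin CLI.
# Precedence: --set overrides > this file > package defaults.
output_dir: cuporigin-out

paths:
  expression: cuporigin-out/expression.tsv
  metadata: cuporigin-out/metadata.tsv
  gmt: cuporigin-out/gene_sets.gmt
  enrichment: cuporigin-out/enrichment.tsv
  selection: cuporigin-out/selection.tsv
  model: cuporigin-out/model.rds
  predictions: cuporigin-out/predictions.tsv

synth:
  n_genes: 500
  n_classes: 4
  samples_per_class_per_platform: 10
  n_gene_sets: 80
  seed: 1

enrichment:
  min_set_size: 5
  n_null: 100
  seed: 13

selection:
  positive_platform: microarray
  delta: 0.25

training:
  grid: small        # "default", "small", or an inline grid mapping
  cv_folds: 3
  seed: 1
  balanced: false

evaluation:
  ks: [1, 2]
  deltas: [0.1, 0.25]
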