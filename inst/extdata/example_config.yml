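# Example sandfix pipeline configuration.
# Omit `input:` to run on a synthetic study drawn from the default design.
seed: 20
rho: 0.5
eigen_min: 1
cum_min: 85
# input:
#   quadrats: quadrats.csv
#   soil: soil.csv
polarity:
  dominant_iv: positive
rf:
  train_fraction: 0.7
  cv_folds: 5
  mtry_min: 3
  mtry_max: 15
  n_trees: 500
  n_permutations: 1000
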