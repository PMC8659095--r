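# Default hyperparameter grids for the ligand-only baseline regressors.
# Small, fixed grids searched by k-fold cross-validated squared error.
lasso:
  lambda: [0.0001, 0.001, 0.01, 0.1, 1.0]
knn:
  k: [3, 5, 10, 20]
decision_tree:
  cp: [0.001, 0.01, 0.05]
random_forest:
  num_trees: [300]
  mtry_frac: [0.33, 0.6]
gradient_boosting:
  nrounds: [50, 200]
  max_depth: [2, 4]
  eta: [0.1]
svr:
  cost: [0.1, 1.0, 10.0]
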