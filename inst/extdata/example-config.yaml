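# Example pipeline configuration for the `pannen` CLI.
# All keys are optional; shown values are the defaults.

cohort_dir: cohort        # where `simulate` writes / `extract` reads patients
out_dir: results          # features.csv and report/ go here

# phantom cohort composition (G1, G2, G3)
n_per_grade: [31, 52, 17]
master_seed: 1

# texture analysis
thickness: 5              # mm, through-plane standardization
n_bins: 128               # entropy histogram bins
range_mode: mask_min_max  # or fixed_window / mu_pm_3sigma

# statistics
alpha: 0.05
cutoffs: {}               # optional per-feature ROC cutoffs, e.g. kurtosis: 0.8
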