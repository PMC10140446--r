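# Example pipeline configuration for a small synthetic run.
# Any field omitted here falls back to the package default; per-stage seeds
# derive from the global seed by fixed offsets when unset.
seed: 1
outdir: normdev_run
stages:
  synthesize: true
  cognition: true
  normative: true
  clinical: true
  pgs: true
  associate: true
  enrich: true
synthesize:
  n_subjects: 800
  n_snps: 200
  cognitive_missing_rate: 0.01
  item_missing_rate: 0.02
normative:
  k: 5
  n_restarts: 3
  max_opt_n: 1000
clinical:
  k: 7
  n_restarts: 10
pgs:
  n_thresholds: 500
associate:
  prior_sd: 0.5
enrich:
  thresholds_sd: [1, 1.5, 2, 3]
  correction: false
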