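# Full Monte-Carlo acceptance suite. Bands are 3-SE binomial bands around
# the nominal rates; scenario sizes are desk-scale (minutes on one CPU).
name: acceptance
scenarios:
  - name: recovery
    analysis: recovery
    n_replicates: 200
    n_individuals: 20000
    hr50_grid: [0.7, 0.9, 1.0]
  - name: coverage
    analysis: recovery
    n_replicates: 1000
    n_individuals: 2000
    hr50_grid: [0.8]
  - name: type1
    analysis: type1
    n_replicates: 1000
    n_individuals: 5000
  - name: power
    analysis: power
    n_replicates: 250
    n_individuals: 5000
    effect_grid: [0, 0.05, 0.1, 0.15]
  - name: additivity
    analysis: additivity
    n_replicates: 200
    n_individuals: 10000
    hr50_a: 0.8
    hr50_b: 0.75
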