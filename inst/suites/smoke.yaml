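# Tiny suite for quick end-to-end checks of the experiment harness.
name: smoke
scenarios:
  - name: recovery_smoke
    analysis: recovery
    n_replicates: 5
    n_individuals: 2000
    hr50_grid: [0.8]
  - name: type1_smoke
    analysis: type1
    n_replicates: 5
    n_individuals: 2000
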