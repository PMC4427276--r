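name: case1
title: Ethanol production in S. cerevisiae anaerobic fermentation
model: case1_scerevisiae.json
objective:
  target_flux: V_PK
  f2_subset: [X1, X2, X3, X4, X5, Y1, Y2, Y3, Y4, Y5, Y6]
  reference_state:
    X1: '1'
    X2: '1'
    X3: '1'
    X4: '1'
    X5: '1'
    Y1: '1'
    Y2: '1'
    Y3: '1'
    Y4: '1'
    Y5: '1'
    Y6: '1'
    Y7: '1'
    Y8: '1'
solved: [X1, X2, X3, X4, X5]
preset:
  max_generations: 300
  representative_selection: fitness
  steady_state_mode: penalty
  penalty_weight: 10.0
  stall_generations: 50
  seed: 1
  genetic:
    population_size: 150
    bits_per_variable: 16
    crossover_points: 2
    mutation_rate: 0.3
    elitism_count: 1
  newton:
    max_iterations: 50
    tolerance: 1.0e-6
    damping: 1.0
    max_step: 5.0
metadata:
  reported_best_f1: 52.91
  reported_best_f2: 294.80
  reported_mean_f1: 52.74
  reported_sd_f1: 0.0133
  reported_best_solution: case1_best_reported.json
  comparator_f1: [52.0843, 52.5118, 52.57]
  comparator_f2: [295.27, 297.664, 297.384]
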