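name: case2
title: Tryptophan biosynthesis in E. coli
model: case2_ecoli_trp.json
objective:
  target_flux: V34
  f2_subset: [X1, X2, X3, X4, X5, X6, X8]
  reference_state:
    X1: '1'
    X2: '1'
    X3: '1'
    X4: '0.00312'
    X5: '5'
    X6: '2283'
    X7: '0.011'
    X8: '430'
    X9: '7.5'
    X10: '0.005'
    X11: '0.9'
    X12: '0.02'
    X13: '0'
solved: [X1, X2, X3]
preset:
  max_generations: 350
  representative_selection: fitness
  steady_state_mode: penalty
  penalty_weight: 10.0
  stall_generations: 50
  seed: 1
  genetic:
    population_size: 150
    bits_per_variable: 16
    crossover_points: 1
    mutation_rate: 0.2
    elitism_count: 1
  newton:
    max_iterations: 50
    tolerance: 1.0e-6
    damping: 1.0
    max_step: 5.0
validation_bounds:
  X5: [5, 10]
metadata:
  reported_best_f1: 3.9759
  reported_best_f2: 6006.5581
  reported_mean_f1: 3.9614
  reported_sd_f1: 0.0032
  reported_best_solution: case2_best_reported.json
  comparator_f1: [3.0620, 3.0620, 3.9460, 3.9570]
  comparator_f2: [6007.1412, 6007.1540, 6007.1314, 6007.7814]
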