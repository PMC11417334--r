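name: fig5_polyclonal
seed: 20240906
n_cells: 30000.0
marrow:
  host_fraction: 0.0
  donors:
  - genotype: 564Igi-FoxP3-DTR
    parts: 0.3333333
    confetti_labelable: no
    dtx_ablatable: yes
  - genotype: FoxP3-DTR
    parts: 0.3333333
    confetti_labelable: no
    dtx_ablatable: yes
  - genotype: FoxP3-Confetti
    parts: 0.3333333
    confetti_labelable: yes
    dtx_ablatable: no
recombination:
  rate: 0.6
  outcome_probs:
  - 0.25
  - 0.25
  - 0.25
  - 0.25
  cassette_copies: 2
n_follicles: 40.0
founders_per_follicle: 12.0
tzone_founders: 60.0
expansion_concentration: 10000.0
go_dark_rate: 0.0
recovery_mode: proportional
homeostatic_target: 2000.0
observation_days:
- 3
- 15
cells_sampled_per_follicle: 300.0
min_cells: 5.0
dtx:
  start_day: 4.0
  every_k_days: 3.0
  ablation_efficiency: 0.5
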