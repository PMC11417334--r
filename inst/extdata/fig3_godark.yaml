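name: fig3_godark
seed: 20240904
n_cells: 20000.0
marrow:
  host_fraction: 0.0
  donors:
  - genotype: 564Igi
    parts: 0.3333333
    confetti_labelable: no
    dtx_ablatable: no
  - genotype: FoxP3-Confetti
    parts: 0.6666667
    confetti_labelable: yes
    dtx_ablatable: no
recombination:
  rate: 0.2
  outcome_probs:
  - 0.25
  - 0.25
  - 0.25
  - 0.25
  cassette_copies: 2
n_follicles: 40.0
founders_per_follicle: 4.0
tzone_founders: 60.0
expansion_concentration: 1000000.0
go_dark_rate: 0.06
recovery_mode: proportional
homeostatic_target: 300.0
observation_days:
- 4
- 18
- 32
cells_sampled_per_follicle: 300.0
min_cells: 5.0
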