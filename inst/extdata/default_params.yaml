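plastochron: 1.5
germination_day: 3.0
senescence_age: 40.0
lamina_wmax: 30.0
lamina_te: 20.0
lamina_tm: 8.0
petiole_wmax: 8.0
petiole_te: 15.0
petiole_tm: 6.0
sla: 3.0e-05
petiole_density: 500.0
lamina_init_mg: 0.1
petiole_init_mg: 0.02
root_init_mg: 0.05
root_sink_fraction: 0.1
surplus_root_fraction: 0.5
seed_reserve_mg: 2.0
seed_reserve_days: 6.0
p_max: 14.0
phi: 0.05
carbon_conversion: 0.03
init_angle: 25.0
angle_step: 16.0
angle_max: 80.0
touch_distance: 0.002
rfr_angle_threshold: 0.5
hyponasty_growth_only: yes
divergence_angle: 137.5
lamina_aspect: 2.0
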