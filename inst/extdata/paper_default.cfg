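name = paper_default
n_animals = 18
seed = 1
urt_depth_log_mean = 10.8197782844103
urt_depth_log_sd = 0.3
unique_depth_log_mean = 5.7037824746562
unique_depth_log_sd = 0.5
aspirate_depth_log_mean = 7.60090245954208
aspirate_depth_log_sd = 0.4
background_depth_log_mean = 2.70805020110221
background_depth_log_sd = 0.5
env_depth_log_mean = 8.51719319141624
env_depth_log_sd = 0.3
urt_dispersion = 500
unique_dispersion = 20
aspirate_dispersion = 100
background_dispersion = 20
env_dispersion = 100
frac_background = 0.333333333333333
frac_unique = 0.583333333333333
frac_aspirate = 0.0833333333333333
n_reagent = 8
n_ntc = 3
n_env = 3
contaminant_load = 100
reagent_load = 800
ntc_load = 30
read_length = 150
error_rate = 0.002
reference_length = 254
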