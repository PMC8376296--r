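variable,factor1,factor2,factor3,factor4,factor5,rep_score_printed
radial_velocity_max,0.94,0.25,0.16,0.01,-0.03,0.55
radial_velocity_sd,0.92,0.14,0.13,0.30,0.00,0.36
speed_sd,0.88,0.10,0.37,0.22,0.00,0.18
speed_max,0.88,0.24,0.39,-0.02,0.02,0.25
move_duration_s,0.09,0.95,0.06,-0.07,0.08,0.78
path_length_mm,0.34,0.82,0.29,0.33,0.05,-0.18
latency_max_speed_s,0.04,0.77,0.09,-0.08,-0.02,0.73
latency_max_accel_s,0.04,0.75,0.08,-0.09,0.00,0.72
max_path_deviation_mm,0.21,0.66,0.28,0.58,0.10,-0.50
angular_velocity_sd,0.39,0.12,0.87,0.17,0.00,0.19
angular_velocity_max,0.45,0.23,0.82,-0.02,0.19,-0.02
angular_velocity_mean,0.18,0.23,0.74,0.45,-0.38,0.26
turn_efficiency,0.01,0.04,0.04,-0.20,0.02,NA
radial_velocity_mean,0.54,0.20,0.14,0.77,0.20,-0.30
speed_mean,0.49,0.24,0.37,0.75,0.01,-0.36
path_efficiency,-0.03,-0.02,0.11,0.48,-0.02,0.43
movement_onset_latency_s,-0.12,0.01,-0.04,-0.15,0.01,NA
net_heading_change_rad,-0.01,-0.03,0.00,-0.01,0.01,NA
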