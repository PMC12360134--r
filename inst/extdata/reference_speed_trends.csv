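speed_bl,tbf_mean,tbf_sd,wave_speed_mean,wave_speed_sd,fin_effort_mean,fin_effort_sd,body_angle_mean,body_angle_sd
0.5,2.17,0.38,1.12,0.32,0.44,0.11,39.4,11.5
0.75,2.04,0.39,1.11,0.20,0.41,0.08,44.6,2.15
1,2.32,0.47,1.21,0.31,0.37,0.02,39.6,9.95
1.25,2.20,0.29,1.25,0.37,0.41,0.07,41.9,3.18
1.5,2.20,0.20,1.24,0.15,0.44,0.08,39.0,3.41
1.75,2.49,0.35,1.33,0.11,0.48,0.07,39.0,4.53
2,2.44,0.32,1.37,0.17,0.46,0.12,34.8,3.47
3,3.00,0.38,1.71,0.31,0.50,0.02,28.5,3.99
4,3.24,0.45,1.74,0.36,0.57,0.08,23.5,3.22
5,3.77,0.68,2.32,0.34,0.63,0.07,19.2,1.51
6,3.66,0.25,2.52,0.35,0.57,0.04,14.0,3.34
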