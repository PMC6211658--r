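lambda_label,ki_per_s,t_half_label,k_minus_i_per_s,kd_nM,koff_per_s,kon_ss_M_per_s
"83,333 hr",1e-8,"19,254 hr",1e-8,1,NA,NA
833 hr,1e-6,192.5 hr,1e-6,1,1e-5,1e4
83 hr,1e-5,19.25 hr,1e-5,1,1e-4,1e5
8.33 hr,1e-4,1.9 hr,1e-4,1,1e-3,1e6
50 min,1e-3,11.6 min,1e-3,1,1e-2,1e7
5 min,1e-2,1.16 min,1e-2,1,1e-1,1e8
30 s,1e-1,6.9 s,1e-1,1,1e0,1e9
3 s,1e0,0.69 s,1e0,1,1e1,1e10
300 ms,1e1,69 ms,1e1,1,1e2,1e11
199 hr,1e-4,1.9 hr,1e-6,1,1e-3,1e6
20 hr,8e-4,14.4 min,1e-5,1,1e-2,1e7
2.1 hr,3e-3,3.9 min,1e-4,1,1e-1,1e8
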