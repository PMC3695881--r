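group,network,term,estimate,stderr,ratio_printed
low_cost,1,two_star,0.04,0.01,6.25
low_cost,2,two_star,0.12,0.04,2.66
low_cost,3,two_star,-0.04,0.04,-0.97
low_cost,4,two_star,0.03,0.01,2.02
low_cost,5,two_star,-0.02,0.02,-0.84
low_cost,1,three_star,0.00,0.00,0.24
low_cost,2,three_star,0.00,0.00,0.86
low_cost,3,three_star,0.01,0.00,2.55
low_cost,4,three_star,0.00,0.00,-0.41
low_cost,5,three_star,0.00,0.00,3.03
low_cost,1,alt_k_star,-1.95,0.42,-4.60
low_cost,2,alt_k_star,-2.39,1.24,-1.92
low_cost,3,alt_k_star,-1.24,0.61,-2.01
low_cost,4,alt_k_star,-1.36,0.38,-3.58
low_cost,5,alt_k_star,-3.55,1.23,-2.89
low_cost,1,alt_k_triangle,1.28,0.10,12.64
low_cost,2,alt_k_triangle,-0.05,0.07,-0.73
low_cost,3,alt_k_triangle,1.37,0.19,7.04
low_cost,4,alt_k_triangle,1.64,0.14,11.54
low_cost,5,alt_k_triangle,1.43,0.11,12.68
low_cost,1,alt_k_two_path,-0.05,0.01,-5.70
low_cost,2,alt_k_two_path,-0.17,0.03,-6.02
low_cost,3,alt_k_two_path,-0.17,0.02,-7.98
low_cost,4,alt_k_two_path,-0.02,0.02,-0.85
low_cost,5,alt_k_two_path,-0.14,0.01,-15.40
high_cost,1,two_star,0.04,0.00,19.35
high_cost,2,two_star,0.03,0.00,13.71
high_cost,3,two_star,0.02,0.00,9.53
high_cost,4,two_star,-0.04,0.03,-1.34
high_cost,5,two_star,0.08,0.01,7.19
high_cost,1,three_star,0.00,0.00,-3.84
high_cost,2,three_star,0.00,0.00,-1.74
high_cost,3,three_star,0.00,0.00,-1.10
high_cost,4,three_star,0.00,0.00,2.58
high_cost,5,three_star,0.00,0.00,-0.77
high_cost,1,alt_k_star,-5.45,1.03,-5.28
high_cost,2,alt_k_star,-5.05,1.14,-4.44
high_cost,3,alt_k_star,-3.30,0.55,-5.96
high_cost,4,alt_k_star,-9.60,8.41,-1.14
high_cost,5,alt_k_star,-3.68,1.30,-2.83
high_cost,1,alt_k_triangle,0.76,0.06,11.74
high_cost,2,alt_k_triangle,1.06,0.08,12.72
high_cost,3,alt_k_triangle,1.72,0.08,20.66
high_cost,4,alt_k_triangle,-0.43,0.06,-6.59
high_cost,5,alt_k_triangle,0.33,0.09,3.51
high_cost,1,alt_k_two_path,-0.05,0.00,-14.60
high_cost,2,alt_k_two_path,-0.06,0.00,-13.60
high_cost,3,alt_k_two_path,-0.04,0.00,-7.76
high_cost,4,alt_k_two_path,-0.23,0.02,-11.99
high_cost,5,alt_k_two_path,-0.07,0.01,-5.40
low_readmission,1,two_star,-0.81,1.78,-0.45
low_readmission,2,two_star,0.05,0.03,1.76
low_readmission,3,two_star,0.01,0.06,0.21
low_readmission,4,two_star,0.03,0.02,1.41
low_readmission,5,two_star,0.02,0.09,0.16
low_readmission,1,three_star,0.08,0.42,0.18
low_readmission,2,three_star,0.00,0.00,1.75
low_readmission,3,three_star,0.01,0.00,1.89
low_readmission,4,three_star,0.00,0.00,1.40
low_readmission,5,three_star,0.01,0.01,1.06
low_readmission,1,alt_k_star,0.15,2.98,0.05
low_readmission,2,alt_k_star,-1.76,0.77,-2.28
low_readmission,3,alt_k_star,-5.05,1.94,-2.60
low_readmission,4,alt_k_star,-3.21,0.89,-3.61
low_readmission,5,alt_k_star,-0.19,0.98,-0.20
low_readmission,1,alt_k_triangle,1.31,0.33,3.93
low_readmission,2,alt_k_triangle,0.68,0.12,5.49
low_readmission,3,alt_k_triangle,0.70,0.14,4.94
low_readmission,4,alt_k_triangle,1.71,0.19,8.79
low_readmission,5,alt_k_triangle,-0.02,0.11,-0.20
low_readmission,1,alt_k_two_path,0.17,0.36,0.46
low_readmission,2,alt_k_two_path,-0.11,0.03,-4.05
low_readmission,3,alt_k_two_path,-0.24,0.02,-13.12
low_readmission,4,alt_k_two_path,-0.11,0.01,-9.88
low_readmission,5,alt_k_two_path,-0.16,0.06,-2.76
high_readmission,1,two_star,0.02,0.01,0.05
high_readmission,2,two_star,0.06,0.01,-0.03
high_readmission,3,two_star,-0.02,0.01,0.02
high_readmission,4,two_star,0.05,0.03,0.04
high_readmission,5,two_star,0.30,0.26,-0.17
high_readmission,1,three_star,0.00,0.00,0.07
high_readmission,2,three_star,0.00,0.00,0.05
high_readmission,3,three_star,0.00,0.00,0.08
high_readmission,4,three_star,0.00,0.00,0.04
high_readmission,5,three_star,-0.02,0.02,-0.17
high_readmission,1,alt_k_star,-5.23,1.29,0.04
high_readmission,2,alt_k_star,-8.65,1.25,-0.02
high_readmission,3,alt_k_star,-6.65,2.47,0.05
high_readmission,4,alt_k_star,-7.54,2.95,0.01
high_readmission,5,alt_k_star,-26.01,11.73,-0.34
high_readmission,1,alt_k_triangle,0.48,0.11,-0.02
high_readmission,2,alt_k_triangle,0.97,0.10,0.01
high_readmission,3,alt_k_triangle,0.46,0.12,-0.01
high_readmission,4,alt_k_triangle,0.97,0.15,0.03
high_readmission,5,alt_k_triangle,-0.07,0.07,-0.34
high_readmission,1,alt_k_two_path,-0.15,0.01,0.05
high_readmission,2,alt_k_two_path,-0.11,0.00,0.05
high_readmission,3,alt_k_two_path,-0.18,0.01,0.09
high_readmission,4,alt_k_two_path,-0.11,0.02,-0.04
high_readmission,5,alt_k_two_path,-0.33,0.01,0.09
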