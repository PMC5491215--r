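neuron,n,total_length,mean_intensity,circumradius,branch_points
1,2750,2182.42,1.26,237.48,16
2,3019,3073.93,0.98,325.49,22
3,2195,1852.01,1.19,231.55,18
4,2599,2123.39,1.22,261.55,19
5,3660,3254.50,1.12,332.11,23
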