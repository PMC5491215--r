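neuron,n,total_length,mean_intensity,circumradius,branch_points
1,1889,1527.45,1.24,257.74,8
1,584,615.79,0.95,208.72,3
1,1214,957.66,1.27,225.92,5
1,1272,1156.29,1.10,235.34,7
2,287,391.74,0.73,137.46,4
2,791,928.87,0.85,220.23,11
2,270,327.29,0.82,139.79,2
3,852,664.26,1.28,237.90,3
3,2149,1467.43,1.46,209.18,8
3,662,594.30,1.11,177.59,4
4,778,556.49,1.40,169.34,4
4,1487,1282.15,1.16,213.84,8
4,1004,834.83,1.20,202.17,5
5,2244,2231.19,1.01,309.20,14
5,978,879.04,1.11,204.76,7
5,1088,851.73,1.28,211.03,6
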