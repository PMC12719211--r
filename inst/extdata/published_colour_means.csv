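blanch_time_min,storage_h,L,a,b,delta_e_printed
0,0,59.7,-2.4,36.0,NA
0,6,56.4,-2.2,34.8,3.9
0,24,49.9,0.7,33.1,10.8
2,0,56.8,-1.8,36.2,NA
2,6,48.4,1.0,28.3,14.2
2,24,33.3,1.6,17.1,32.8
4,0,56.0,-2.0,37.0,NA
4,6,54.9,-1.3,34.0,6.4
4,24,50.7,-0.4,29.1,11.8
6,0,59.0,-2.1,37.7,NA
6,6,58.4,-2.0,35.7,3.3
6,24,56.2,-0.6,31.9,6.1
10,0,60.9,-2.7,39.8,NA
10,6,59.5,-2.3,37.1,2.5
10,24,57.4,-1.2,33.8,4.0
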