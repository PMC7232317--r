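run,class,x_pH,x_temperature,x_time,X_pH,X_temperature,X_time,y_mean,y_se,n_rep
1,factorial,1,1,-1,7,30,4,76,0.88,3
2,center,0,0,0,6,26,5,93,0.57,3
3,axial,0,0,-1.681792830507429,6,26,3.318207169492571,75,1.1,3
4,center,0,0,0,6,26,5,93,1.7,3
5,factorial,1,-1,-1,7,22,4,69,0.57,3
6,factorial,-1,-1,-1,5,22,4,64,0.57,3
7,center,0,0,0,6,26,5,94.5,0.28,3
8,center,0,0,0,6,26,5,95.5,0.28,3
9,factorial,-1,1,-1,5,30,4,73,0,3
10,center,0,0,0,6,26,5,95.599999999999994,0.57,3
11,axial,-1.681792830507429,0,0,4.318207169492571,26,5,76,0.57,3
12,center,0,0,0,6,26,5,93.5,0.57,3
13,center,0,0,0,6,26,5,93,0.57,3
14,axial,0,1.681792830507429,0,6,32.727171322029719,5,75,0.57,3
15,factorial,-1,1,1,5,30,6,79,0.57,3
16,center,0,0,0,6,26,5,94.299999999999997,0.03,3
17,factorial,-1,-1,1,5,22,6,85,0,3
18,axial,0,0,1.681792830507429,6,26,6.681792830507429,85.200000000000003,0.11,3
19,factorial,1,1,1,7,30,6,71,0.6,3
20,axial,0,-1.681792830507429,0,6,19.272828677970285,5,75,0,3
21,factorial,1,-1,1,7,22,6,85,0,3
22,center,0,0,0,6,26,5,95.299999999999997,0.57,3
23,axial,1.681792830507429,0,0,7.681792830507429,26,5,75,0.57,3
24,center,0,0,0,6,26,5,94.5,0.28,3
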