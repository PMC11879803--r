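dataset,class,n_objects,mostly_tracked,partially_tracked,mostly_lost,idf1,idp,idr
123,cluster,91,49,24,18,0.682,0.670,0.695
123,colony,28,15,12,1,0.831,0.927,0.752
123,all,119,64,36,19,0.730,0.746,0.715
124,cluster,103,78,14,11,0.764,0.696,0.847
124,colony,14,14,0,0,0.887,0.839,0.940
124,all,117,93,14,10,0.788,0.719,0.872
125,cluster,80,51,17,12,0.749,0.713,0.789
125,colony,31,10,17,4,0.704,0.800,0.629
125,all,111,62,36,13,0.744,0.751,0.738
127,cluster,112,64,37,11,0.715,0.690,0.739
127,colony,39,21,17,1,0.799,0.835,0.766
127,all,150,85,54,11,0.748,0.739,0.753
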