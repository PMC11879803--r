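class,images,instances,precision,recall,map50,map50_95
all,29,1423,0.722,0.594,0.668,0.451
candidate,18,165,0.565,0.236,0.392,0.27
cell,27,742,0.819,0.58,0.697,0.356
cluster,28,431,0.647,0.724,0.722,0.492
colony,22,85,0.855,0.835,0.861,0.685
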