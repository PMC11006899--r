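"electrode_id","x_um","y_um","compartment"
1,0,0,"LEFT"
2,150,0,"LEFT"
3,300,0,"LEFT"
4,0,150,"LEFT"
5,150,150,"LEFT"
6,300,150,"LEFT"
7,0,300,"LEFT"
8,150,300,"LEFT"
9,1800,0,"RIGHT"
10,1950,0,"RIGHT"
11,2100,0,"RIGHT"
12,1800,150,"RIGHT"
13,1950,150,"RIGHT"
14,2100,150,"RIGHT"
15,1800,300,"RIGHT"
16,1950,300,"RIGHT"
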