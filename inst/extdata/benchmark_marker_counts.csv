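# Published benchmark: segregating-variant counts in four simulated pig populations by marker-density level.
proportion,population,count,density_per_kb
total,P1,212696,21.4
total,P2,214899,21.4
total,P3,216366,21.4
total,P4,213389,21.4
0.01,P1,2126,0.2
0.01,P2,2148,0.2
0.01,P3,2163,0.2
0.01,P4,2133,0.2
0.05,P1,10634,1.1
0.05,P2,10744,1.1
0.05,P3,10818,1.1
0.05,P4,10669,1.1
0.1,P1,21269,2.1
0.1,P2,21489,2.1
0.1,P3,21636,2.1
0.1,P4,21338,2.1
0.3,P1,63808,6.4
0.3,P2,64469,6.4
0.3,P3,64909,6.4
0.3,P4,64016,6.4
0.5,P1,106348,10.7
0.5,P2,107449,10.7
0.5,P3,108183,10.7
0.5,P4,106694,10.7
0.9,P1,191426,19.3
0.9,P2,193409,19.3
0.9,P3,194729,19.3
0.9,P4,192050,19.3
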