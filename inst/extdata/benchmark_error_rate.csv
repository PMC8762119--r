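# Published benchmark cells: factorial imputation accuracy study on simulated pig sequence data (LCWGS panels).
method,scheme,reference_size,proportion,value
beagle5.1,lcwgs,100,0.01,19.15
beagle5.1,lcwgs,100,0.05,11.76
beagle5.1,lcwgs,100,0.1,5.77
beagle5.1,lcwgs,100,0.3,1.15
beagle5.1,lcwgs,100,0.5,0.53
beagle5.1,lcwgs,100,0.9,0.16
beagle5.1,lcwgs,1000,0.01,18.44
beagle5.1,lcwgs,1000,0.05,6.55
beagle5.1,lcwgs,1000,0.1,1.91
beagle5.1,lcwgs,1000,0.3,0.43
beagle5.1,lcwgs,1000,0.5,0.23
beagle5.1,lcwgs,1000,0.9,0.09
beagle5.1,lcwgs,3000,0.01,18.27
beagle5.1,lcwgs,3000,0.05,2.99
beagle5.1,lcwgs,3000,0.1,0.98
beagle5.1,lcwgs,3000,0.3,0.22
beagle5.1,lcwgs,3000,0.5,0.12
beagle5.1,lcwgs,3000,0.9,0.05
beagle5.1,lcwgs,5000,0.01,18.2
beagle5.1,lcwgs,5000,0.05,2.03
beagle5.1,lcwgs,5000,0.1,0.68
beagle5.1,lcwgs,5000,0.3,0.15
beagle5.1,lcwgs,5000,0.5,0.08
beagle5.1,lcwgs,5000,0.9,0.04
beagle5.1,lcwgs,10000,0.01,18.1
beagle5.1,lcwgs,10000,0.05,1.17
beagle5.1,lcwgs,10000,0.1,0.41
beagle5.1,lcwgs,10000,0.3,0.09
beagle5.1,lcwgs,10000,0.5,0.05
beagle5.1,lcwgs,10000,0.9,0.02
minimac4,lcwgs,100,0.01,17.25
minimac4,lcwgs,100,0.05,11.41
minimac4,lcwgs,100,0.1,9.01
minimac4,lcwgs,100,0.3,6.83
minimac4,lcwgs,100,0.5,7.09
minimac4,lcwgs,100,0.9,21.26
minimac4,lcwgs,1000,0.01,16.36
minimac4,lcwgs,1000,0.05,10.8
minimac4,lcwgs,1000,0.1,8.64
minimac4,lcwgs,1000,0.3,6.79
minimac4,lcwgs,1000,0.5,7.24
minimac4,lcwgs,1000,0.9,23.31
minimac4,lcwgs,3000,0.01,16.0
minimac4,lcwgs,3000,0.05,10.72
minimac4,lcwgs,3000,0.1,8.65
minimac4,lcwgs,3000,0.3,6.88
minimac4,lcwgs,3000,0.5,7.39
minimac4,lcwgs,3000,0.9,24.33
minimac4,lcwgs,5000,0.01,15.85
minimac4,lcwgs,5000,0.05,10.7
minimac4,lcwgs,5000,0.1,8.68
minimac4,lcwgs,5000,0.3,6.93
minimac4,lcwgs,5000,0.5,7.46
minimac4,lcwgs,5000,0.9,24.8
minimac4,lcwgs,10000,0.01,15.67
minimac4,lcwgs,10000,0.05,10.7
minimac4,lcwgs,10000,0.1,8.74
minimac4,lcwgs,10000,0.3,7.02
minimac4,lcwgs,10000,0.5,7.58
minimac4,lcwgs,10000,0.9,25.46
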