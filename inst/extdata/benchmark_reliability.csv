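# Published benchmark cells: factorial imputation accuracy study on simulated pig sequence data (LCWGS panels).
method,scheme,reference_size,proportion,value
beagle5.1,lcwgs,100,0.01,0.21
beagle5.1,lcwgs,100,0.05,0.56
beagle5.1,lcwgs,100,0.1,0.8
beagle5.1,lcwgs,100,0.3,0.97
beagle5.1,lcwgs,100,0.5,0.99
beagle5.1,lcwgs,100,0.9,1.0
beagle5.1,lcwgs,1000,0.01,0.25
beagle5.1,lcwgs,1000,0.05,0.78
beagle5.1,lcwgs,1000,0.1,0.94
beagle5.1,lcwgs,1000,0.3,0.99
beagle5.1,lcwgs,1000,0.5,1.0
beagle5.1,lcwgs,1000,0.9,1.0
beagle5.1,lcwgs,3000,0.01,0.26
beagle5.1,lcwgs,3000,0.05,0.9
beagle5.1,lcwgs,3000,0.1,0.97
beagle5.1,lcwgs,3000,0.3,0.99
beagle5.1,lcwgs,3000,0.5,1.0
beagle5.1,lcwgs,3000,0.9,1.0
beagle5.1,lcwgs,5000,0.01,0.26
beagle5.1,lcwgs,5000,0.05,0.94
beagle5.1,lcwgs,5000,0.1,0.98
beagle5.1,lcwgs,5000,0.3,1.0
beagle5.1,lcwgs,5000,0.5,1.0
beagle5.1,lcwgs,5000,0.9,1.0
beagle5.1,lcwgs,10000,0.01,0.27
beagle5.1,lcwgs,10000,0.05,0.96
beagle5.1,lcwgs,10000,0.1,0.99
beagle5.1,lcwgs,10000,0.3,1.0
beagle5.1,lcwgs,10000,0.5,1.0
beagle5.1,lcwgs,10000,0.9,1.0
minimac4,lcwgs,100,0.01,0.14
minimac4,lcwgs,100,0.05,0.47
minimac4,lcwgs,100,0.1,0.63
minimac4,lcwgs,100,0.3,0.82
minimac4,lcwgs,100,0.5,0.88
minimac4,lcwgs,100,0.9,0.94
minimac4,lcwgs,1000,0.01,0.2
minimac4,lcwgs,1000,0.05,0.58
minimac4,lcwgs,1000,0.1,0.72
minimac4,lcwgs,1000,0.3,0.86
minimac4,lcwgs,1000,0.5,0.9
minimac4,lcwgs,1000,0.9,0.95
minimac4,lcwgs,3000,0.01,0.25
minimac4,lcwgs,3000,0.05,0.63
minimac4,lcwgs,3000,0.1,0.74
minimac4,lcwgs,3000,0.3,0.87
minimac4,lcwgs,3000,0.5,0.91
minimac4,lcwgs,3000,0.9,0.95
minimac4,lcwgs,5000,0.01,0.28
minimac4,lcwgs,5000,0.05,0.64
minimac4,lcwgs,5000,0.1,0.75
minimac4,lcwgs,5000,0.3,0.87
minimac4,lcwgs,5000,0.5,0.91
minimac4,lcwgs,5000,0.9,0.95
minimac4,lcwgs,10000,0.01,0.33
minimac4,lcwgs,10000,0.05,0.67
minimac4,lcwgs,10000,0.1,0.77
minimac4,lcwgs,10000,0.3,0.87
minimac4,lcwgs,10000,0.5,0.91
minimac4,lcwgs,10000,0.9,0.95
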