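label,group,expected,examiner1,examiner2,examiner3
500 Hz peak 1 latency (ms),marking,0.5,0.5,0.5,0.5
1000 Hz peak 1 latency (ms),marking,0.25,0.25,0.25,0.25
2000 Hz peak 1 latency (ms),marking,0.12,0.12,0.12,0.12
all frequencies peak 1 amplitude (uV),marking,10,10,10,10
500 Hz trough 1 latency (ms),marking,1.5,1.5,1.5,1.5
1000 Hz trough 1 latency (ms),marking,0.75,0.74,0.74,0.75
2000 Hz trough 1 latency (ms),marking,0.37,0.37,0.37,0.37
all frequencies trough 1 amplitude (uV),marking,-10,-10,-10,-10
500 Hz zero-cross (ms),marking,1,1,1,1
1000 Hz zero-cross (ms),marking,0.5,0.5,0.5,0.5
2000 Hz zero-cross (ms),marking,0.25,0.25,0.25,0.25
500 Hz area under the curve (uV.ms),calculation,6.36,6.33,6.33,6.33
1000 Hz area under the curve (uV.ms),calculation,3.18,3.05,3.05,3.15
2000 Hz area under the curve (uV.ms),calculation,1.59,1.56,1.56,1.56
500 Hz area of two triangles (uV.ms),calculation,5,5,5,5
1000 Hz area of two triangles (uV.ms),calculation,2.5,2.5,2.5,2.5
2000 Hz area of two triangles (uV.ms),calculation,1.25,1.25,1.25,1.25
500 Hz slope (uV/ms),calculation,20,20,20,20
1000 Hz slope (uV/ms),calculation,40,40.81,40.81,40
2000 Hz slope (uV/ms),calculation,80,80,80,80
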