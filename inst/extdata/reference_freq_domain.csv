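label,group,expected,examiner1,examiner2,examiner3
500 Hz FFT frequency (Hz),fft,500,502.07,502.07,500
500 Hz FFT amplitude (uV),fft,10,10,10,10
1000 Hz FFT frequency (Hz),fft,1000,998.96,998.96,1000
1000 Hz FFT amplitude (uV),fft,10,10,10,10
2000 Hz FFT frequency (Hz),fft,2000,1997.93,1997.93,2000
2000 Hz FFT amplitude (uV),fft,10,10,10,10
sum FFT peak 1 frequency (Hz),fft,500,502.07,502.07,500
sum FFT peak 1 amplitude (uV),fft,10,10,10,10
sum FFT peak 2 frequency (Hz),fft,1000,998.96,998.96,1000
sum FFT peak 2 amplitude (uV),fft,10,10,10,10
sum FFT peak 3 frequency (Hz),fft,2000,1997.93,1997.93,2000
sum FFT peak 3 amplitude (uV),fft,10,10,10,10
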