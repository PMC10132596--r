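wavelength,lower,mean,upper
240,0.71,0.97,1.22
250,0.44,0.62,0.79
260,0.46,0.63,0.80
270,0.40,0.54,0.68
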