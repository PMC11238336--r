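frequency: f_Hz
gPrime: Gp_Pa
gDoublePrime: Gpp_Pa
frequencyUnit: Hz
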