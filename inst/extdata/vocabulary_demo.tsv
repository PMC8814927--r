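concept	type
C01	disease
C02	medication
C03	disease
C04	procedure
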