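((cer:0.25,par:0.25):0.15,mik:0.45,bay:0.6);
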