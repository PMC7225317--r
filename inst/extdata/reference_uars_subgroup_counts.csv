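group,above_threshold,below_threshold
uars,43,13
normal_snoring,25,96
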