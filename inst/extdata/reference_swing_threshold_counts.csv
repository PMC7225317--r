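dataset,group,above_threshold,below_threshold
training,uars_osa,57,14
training,normal_snoring,24,95
test,uars_osa,44,15
test,normal_snoring,33,86
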