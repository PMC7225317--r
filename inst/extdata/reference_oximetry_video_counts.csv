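oximetry_category,normal_ps,uars_osa
normal,153,43
inconclusive,180,69
abnormal,6,70
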