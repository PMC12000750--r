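gene,condition,ct_reference,ct_target
IL6,control,9.8,27.4
IL6,inflamed,9.7,22.1
IL8,control,9.9,26.8
IL8,inflamed,9.8,21.3
CCL2,control,9.8,24.9
CCL2,inflamed,9.9,22.6
MMP1,control,9.7,25.2
MMP1,inflamed,9.8,21.9
MMP13,control,9.9,24.1
MMP13,inflamed,9.7,21.5
ACAN,control,9.8,22.7
ACAN,inflamed,9.9,25.6
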