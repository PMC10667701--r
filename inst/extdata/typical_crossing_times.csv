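condition,te_min
control,110
control,80
control,120
control,110
quinine,285
quinine,280
quinine,210
quinine,150
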