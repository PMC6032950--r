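classifier,tp,fp,fn,tn
alert_line,110,4053,84,4242
action_line,38,1230,156,7065
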