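model,tp,fp,fn,tn
cej_bone_level,508,234,11,17877
teeth,983,589,11,18687
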