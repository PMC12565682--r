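l2_combination,n
Spine,601
Spine;Whole-body,536
Ribcage;Spine,314
Ribcage;Spine;Whole-body,86
Ribcage,58
Ribcage;Whole-body,35
Whole-body,21
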