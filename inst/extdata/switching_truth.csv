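id,boundary_index,class_before,class_after
switch,151,normal,directed
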