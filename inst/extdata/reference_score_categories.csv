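group,category,n
non_cad,low,62
non_cad,intermediate,37
non_cad,high,25
non_obstructive,low,12
non_obstructive,intermediate,6
non_obstructive,high,23
obstructive,low,6
obstructive,intermediate,20
obstructive,high,37
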