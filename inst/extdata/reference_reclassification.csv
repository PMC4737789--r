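disease,old_category,new_category,n
obstructive,very_low,very_low,1
obstructive,very_low,low,0
obstructive,very_low,moderate,0
obstructive,very_low,high,0
obstructive,low,very_low,0
obstructive,low,low,6
obstructive,low,moderate,8
obstructive,low,high,0
obstructive,moderate,very_low,1
obstructive,moderate,low,2
obstructive,moderate,moderate,8
obstructive,moderate,high,10
obstructive,high,very_low,0
obstructive,high,low,2
obstructive,high,moderate,1
obstructive,high,high,24
non_obstructive_or_non_cad,very_low,very_low,25
non_obstructive_or_non_cad,very_low,low,3
non_obstructive_or_non_cad,very_low,moderate,0
non_obstructive_or_non_cad,very_low,high,0
non_obstructive_or_non_cad,low,very_low,34
non_obstructive_or_non_cad,low,low,25
non_obstructive_or_non_cad,low,moderate,17
non_obstructive_or_non_cad,low,high,0
non_obstructive_or_non_cad,moderate,very_low,9
non_obstructive_or_non_cad,moderate,low,9
non_obstructive_or_non_cad,moderate,moderate,13
non_obstructive_or_non_cad,moderate,high,16
non_obstructive_or_non_cad,high,very_low,0
non_obstructive_or_non_cad,high,low,2
non_obstructive_or_non_cad,high,moderate,1
non_obstructive_or_non_cad,high,high,11
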