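variable,level,stable,slow_decliner,fast_decliner
arm,LEARN,481,35,3
arm,placebo,386,128,49
arm,solanezumab,390,90,67
apoe4_carrier,non-carrier,732,93,31
apoe4_carrier,carrier,525,160,88
sex,male,494,117,37
sex,female,763,136,82
cdr_progression,non-progressor,970,71,14
cdr_progression,progressor,287,182,105
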