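specimen_id,dsl_mm,specimen_type
OUVC 10606,29.26,Fixed
OUVC 10117,29.96,Skeletal
OUVC 10385,46.1,Frozen
OUVC 10386,56.9,Frozen
OUVC 10387,57.6,Frozen
OUVC 10388,61.2,Frozen
OUVC 10389,84.1,Frozen
OUVC 10390,85.4,Frozen
OUVC 10391,87.1,Frozen
OUVC 10629,185.8,Frozen
OUVC 9761,301.5,Frozen
USNM 211232,477.6,Skeletal
USNM 211233,551.6,Skeletal
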