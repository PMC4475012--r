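label,required_on,required_off,priority,variant_only
Th2RIL9+,GATA3;IL10;IL9,,1,TRUE
Th9,IL9,,2,FALSE
Th17R,RORGT;IL10,,3,TRUE
Th17,RORGT;IL21,,4,FALSE
Tfh,BCL6;IL21,,5,FALSE
iTreg,FOXP3;TGFB|IL10,,6,FALSE
Th1R,TBET;TGFB|IL10,,7,FALSE
Th2R,GATA3;TGFB|IL10,,8,FALSE
Th1,TBET;IFNG,,9,FALSE
Th2,GATA3;IL4,,10,FALSE
GATA3+IL4-,GATA3,IL4,11,FALSE
TrFoxp3-,TGFB|IL10,FOXP3;TBET;GATA3;RORGT;BCL6,12,FALSE
Th0,,TBET;GATA3;RORGT;FOXP3;BCL6;TGFB;IL10;IL9,13,FALSE
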