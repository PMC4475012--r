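source,target
IFNG,IL4
IL10,IFNG
IL10,IL4
IL10,IL9
IL10,RORGT
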