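outcome,UHR-,UHR+,Psychosis
UHR-,51,0,0
UHR+,5,92,14
Psychosis,1,9,40
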