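#units=percent
#value_kind=diameter
#length_m=6e-4
#label=Aplectus antarcticus
#supplement=true
position,value
0.1,0.8
12.6,2.2
21,2.3
51,2.4
87,1.9
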