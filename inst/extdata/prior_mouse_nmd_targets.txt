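Atp10d
Lbh
Slc38a6
Tgm2
Notch2
Ywhag
Luc7l
Ptch1
1700025G04Rik
Ptger2
Msrb3
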