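6
methanol template
C   -0.0470000000    0.6640000000    0.0000000000
O   -0.0470000000   -0.7580000000    0.0000000000
H   -1.0920000000    0.9690000000    0.0000000000
H    0.4370000000    1.0800000000    0.8820000000
H    0.4370000000    1.0800000000   -0.8820000000
H    0.8600000000   -1.0570000000    0.0000000000
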