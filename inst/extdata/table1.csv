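id,gene1,gene2,diagnosis
x1,up,up,case
x2,up,down,case
x3,up,up,control
x4,down,down,control
x5,down,up,case
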