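id,g1,g2,g3,rf,diagnosis
q1,low,low,medium,yes,autism
q2,medium,medium,medium,yes,autism
q3,medium,low,medium,yes,autism
q4,medium,low,high,no,autism|control
q5,low,low,high,no,autism|control
q6,low,high,medium,no,control
q7,medium,high,medium,yes,control
q8,medium,high,high,no,control
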