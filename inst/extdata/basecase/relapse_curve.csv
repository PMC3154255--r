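cycle_index,probability
1,0.04
2,0.0369246538554654
3,0.0340857515586485
4,0.0314651144426621
5,0.0290459614829476
6,0.0268128018414256
7,0.0247513356722456
8,0.0228483625539526
9,0.0210916969617219
10,0.0194700902383989
11,0.0179731585646889
12,0.0165913164672633
13,0.0153157154390045
14,0.0141381872783512
15,0.0130511917849216
16,0.0120477684764881
17,0.0111214920181278
18,0.0102664310781422
19,0.00947711034728487
20,0.00874847547808859
21,0.00807586071978622
22,0.0074549590415764
23,0.00688179455292202
24,0.00635269704427683
25,0.00586427848521401
26,0.00541341132946451
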