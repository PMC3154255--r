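cycle_index,probability
1,0.25
2,0.22620935450899
3,0.204682688269495
4,0.185204555170429
5,0.16758001150891
6,0.151632664928158
7,0.137202909023507
8,0.124146325947852
9,0.112332241029305
10,0.10164241493515
11,0.0919698602928606
12,0.0832177709245199
13,0.0752985529780505
14,0.0681329482585031
15,0.0616492409854016
16,0.0557825400371075
17,0.0504741294986638
18,0.0456708810131837
19,0.0413247220553966
20,0.0373921548056588
21,0.0338338208091532
22,0.0306141070632455
23,0.0277007895905835
24,0.0250647109307009
25,0.0226794883223531
26,0.0205212496559747
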