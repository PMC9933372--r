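"age","qx"
62,0.0051579396861091
63,0.00570040493827602
64,0.00629992175903746
65,0.00696249031424018
66,0.00769474181268162
67,0.00850400487347642
68,0.00939837887333972
69,0.0103868150078716
70,0.0114792058781314
71,0.0126864844991139
72,0.0140207337210381
73,0.0154953071585739
74,0.0171249628383053
75,0.0189260109020212
76,0.0209164768440965
77,0.0231162819166981
78,0.0255474425083727
79,0.0282342904914631
80,0.0312037167436648
81,0.0344854402809685
82,0.0381123056955609
83,0.0421206118755428
84,0.0465504752964017
85,0.051446231520182
86,0.0568568789206918
87,0.0628365690756969
88,0.0694451487341118
89,0.0767487587823783
90,0.0848204962046874
91,0.0937411456621664
92,0.103599988012919
93,0.114495693864864
94,0.12653731110434
95,0.139845356284008
96,0.154553020793013
97,0.170807503881178
98,0.188771485878572
99,1
100,1
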