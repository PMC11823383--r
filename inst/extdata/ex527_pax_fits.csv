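treatment,cell_line,arm,slope,intercept,r_squared
T47D_EX527,T47D,EX527,2.6621,1.0863,0.992
MCF7_EX527,MCF7,EX527,4.3531,-3.4047,0.961
MDA-MB-231_EX527,MDA-MB-231,EX527,2.2873,1.0965,0.995
BT-549_EX527,BT-549,EX527,2.2979,1.0988,0.989
MDA-MB-468_EX527,MDA-MB-468,EX527,2.8225,0.6991,0.962
T47D_mix,T47D,EX527:PAX,1.3282,2.7348,0.9499
MCF7_mix,MCF7,EX527:PAX,1.3686,2.9586,0.899
MDA-MB-231_mix,MDA-MB-231,EX527:PAX,2.4277,1.1523,0.958
BT-549_mix,BT-549,EX527:PAX,2.4131,1.4158,0.9588
MDA-MB-468_mix,MDA-MB-468,EX527:PAX,1.8129,1.9352,0.992
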