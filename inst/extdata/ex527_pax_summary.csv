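cell_line,ic50_mix,sem_mix,n_mix,l_ic50_add,sem_l,u_ic50_add,sem_u,n_add,parallel
MCF7,31.02,7.52,96,22.38,7.44,63.18,8.04,116,FALSE
T47D,29.52,3.29,120,25.38,5.67,NA,NA,188,TRUE
MDA-MB-231,38.45,5.26,96,18.40,7.34,32.55,8.31,164,FALSE
BT-549,30.57,3.760,120,24.93,3.60,NA,NA,140,TRUE
MDA-MB-468,33.40,3.93,96,24.52,4.49,NA,NA,164,TRUE
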