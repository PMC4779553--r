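artery,level,sector,covered
LAD,basal,0,1
LAD,basal,1,1
LAD,basal,2,1
LAD,basal,3,1
LAD,basal,4,1
LAD,basal,5,0
LAD,basal,6,0
LAD,basal,7,0
LAD,basal,8,0
LAD,basal,9,0
LAD,basal,10,0
LAD,basal,11,0
LAD,basal,12,0
LAD,basal,13,0
LAD,basal,14,0
LAD,basal,15,0
LAD,basal,16,0
LAD,basal,17,0
LAD,basal,18,0
LAD,basal,19,1
LAD,basal,20,1
LAD,basal,21,1
LAD,basal,22,1
LAD,basal,23,1
LCx,basal,0,0
LCx,basal,1,0
LCx,basal,2,0
LCx,basal,3,1
LCx,basal,4,1
LCx,basal,5,1
LCx,basal,6,1
LCx,basal,7,1
LCx,basal,8,1
LCx,basal,9,1
LCx,basal,10,1
LCx,basal,11,1
LCx,basal,12,1
LCx,basal,13,0
LCx,basal,14,0
LCx,basal,15,0
LCx,basal,16,0
LCx,basal,17,0
LCx,basal,18,0
LCx,basal,19,0
LCx,basal,20,0
LCx,basal,21,0
LCx,basal,22,0
LCx,basal,23,0
RCA,basal,0,0
RCA,basal,1,0
RCA,basal,2,0
RCA,basal,3,0
RCA,basal,4,0
RCA,basal,5,0
RCA,basal,6,0
RCA,basal,7,0
RCA,basal,8,0
RCA,basal,9,0
RCA,basal,10,0
RCA,basal,11,1
RCA,basal,12,1
RCA,basal,13,1
RCA,basal,14,1
RCA,basal,15,1
RCA,basal,16,1
RCA,basal,17,1
RCA,basal,18,1
RCA,basal,19,1
RCA,basal,20,1
RCA,basal,21,0
RCA,basal,22,0
RCA,basal,23,0
LAD,mid,0,1
LAD,mid,1,1
LAD,mid,2,1
LAD,mid,3,1
LAD,mid,4,1
LAD,mid,5,0
LAD,mid,6,0
LAD,mid,7,0
LAD,mid,8,0
LAD,mid,9,0
LAD,mid,10,0
LAD,mid,11,0
LAD,mid,12,0
LAD,mid,13,0
LAD,mid,14,0
LAD,mid,15,0
LAD,mid,16,0
LAD,mid,17,0
LAD,mid,18,0
LAD,mid,19,1
LAD,mid,20,1
LAD,mid,21,1
LAD,mid,22,1
LAD,mid,23,1
LCx,mid,0,0
LCx,mid,1,0
LCx,mid,2,0
LCx,mid,3,1
LCx,mid,4,1
LCx,mid,5,1
LCx,mid,6,1
LCx,mid,7,1
LCx,mid,8,1
LCx,mid,9,1
LCx,mid,10,1
LCx,mid,11,1
LCx,mid,12,1
LCx,mid,13,0
LCx,mid,14,0
LCx,mid,15,0
LCx,mid,16,0
LCx,mid,17,0
LCx,mid,18,0
LCx,mid,19,0
LCx,mid,20,0
LCx,mid,21,0
LCx,mid,22,0
LCx,mid,23,0
RCA,mid,0,0
RCA,mid,1,0
RCA,mid,2,0
RCA,mid,3,0
RCA,mid,4,0
RCA,mid,5,0
RCA,mid,6,0
RCA,mid,7,0
RCA,mid,8,0
RCA,mid,9,0
RCA,mid,10,0
RCA,mid,11,1
RCA,mid,12,1
RCA,mid,13,1
RCA,mid,14,1
RCA,mid,15,1
RCA,mid,16,1
RCA,mid,17,1
RCA,mid,18,1
RCA,mid,19,1
RCA,mid,20,1
RCA,mid,21,0
RCA,mid,22,0
RCA,mid,23,0
LAD,apical,0,1
LAD,apical,1,1
LAD,apical,2,1
LAD,apical,3,1
LAD,apical,4,1
LAD,apical,5,1
LAD,apical,6,1
LAD,apical,7,0
LAD,apical,8,0
LAD,apical,9,0
LAD,apical,10,0
LAD,apical,11,0
LAD,apical,12,0
LAD,apical,13,0
LAD,apical,14,0
LAD,apical,15,0
LAD,apical,16,0
LAD,apical,17,1
LAD,apical,18,1
LAD,apical,19,1
LAD,apical,20,1
LAD,apical,21,1
LAD,apical,22,1
LAD,apical,23,1
LCx,apical,0,0
LCx,apical,1,0
LCx,apical,2,0
LCx,apical,3,0
LCx,apical,4,0
LCx,apical,5,1
LCx,apical,6,1
LCx,apical,7,1
LCx,apical,8,1
LCx,apical,9,1
LCx,apical,10,1
LCx,apical,11,1
LCx,apical,12,1
LCx,apical,13,0
LCx,apical,14,0
LCx,apical,15,0
LCx,apical,16,0
LCx,apical,17,0
LCx,apical,18,0
LCx,apical,19,0
LCx,apical,20,0
LCx,apical,21,0
LCx,apical,22,0
LCx,apical,23,0
RCA,apical,0,0
RCA,apical,1,0
RCA,apical,2,0
RCA,apical,3,0
RCA,apical,4,0
RCA,apical,5,0
RCA,apical,6,0
RCA,apical,7,0
RCA,apical,8,0
RCA,apical,9,0
RCA,apical,10,0
RCA,apical,11,1
RCA,apical,12,1
RCA,apical,13,1
RCA,apical,14,1
RCA,apical,15,1
RCA,apical,16,1
RCA,apical,17,1
RCA,apical,18,1
RCA,apical,19,0
RCA,apical,20,0
RCA,apical,21,0
RCA,apical,22,0
RCA,apical,23,0
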