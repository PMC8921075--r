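site,tertile,n,low
tf,1,362,71
tf,2,361,90
tf,3,361,97
tr,1,377,54
tr,2,376,74
tr,3,376,86
ls,1,324,99
ls,2,323,118
ls,3,323,119
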