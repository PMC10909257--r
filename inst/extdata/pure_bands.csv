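analyte,center_nm,width_nm,height
PARA,249,15,0.060
PARA,222,10,0.026
ASC,244,13,0.050
ASC,268,15,0.016
CAF,271,13,0.042
CAF,247,15,0.030
CPM,263,12,0.042
CPM,229,11,0.062
CPM,278,13,0.026
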