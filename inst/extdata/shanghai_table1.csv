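district_id,beds,institutions,graded
Pudong,25874,133,86
Huangpu,2935,21,12
Xuhui,6130,41,28
Changning,5892,35,12
Jingan,4475,30,19
Putuo,6645,45,27
Hongkou,7024,35,23
Yangpu,9908,58,31
Minhang,12575,50,30
Baoshan,11735,46,23
Jiading,10279,28,21
Jinshan,7723,30,25
Songjiang,7290,22,16
Qingpu,6282,19,4
Fengxian,5419,27,19
Chongming,6533,38,19
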