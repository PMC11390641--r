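district_id,older_pop,source
Pudong,1080600,published
Yangpu,419800,published
Baoshan,411000,published
Minhang,402400,published
Putuo,380000,published
Huangpu,258437,synthetic
Xuhui,258437,synthetic
Changning,258437,synthetic
Jingan,258437,synthetic
Hongkou,258436,synthetic
Jiading,258436,synthetic
Jinshan,258436,synthetic
Songjiang,258436,synthetic
Qingpu,258436,synthetic
Fengxian,258436,synthetic
Chongming,258436,synthetic
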