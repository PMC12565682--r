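view,n_images,n_normal,n_abnormal,n_abnormalities
Full body-DV,94151,92739,1412,3127
Full body-Lat,72746,70996,1750,5110
Skull-DV,36709,36695,14,29
Skull-Lat,29830,9811,19,49
Forelimbs,26257,26249,8,45
Hindlimbs,1912,1903,9,46
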