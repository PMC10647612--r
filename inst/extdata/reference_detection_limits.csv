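analyte,matrix,lod_mg_per_kg,loq_mg_per_kg
Rebaudioside A,beverage,0.060,0.201
Rebaudioside A,yogurt,0.003,0.011
Rebaudioside A,snack,0.015,0.049
Rebaudioside B,beverage,0.053,0.175
Rebaudioside B,yogurt,0.012,0.041
Rebaudioside B,snack,0.024,0.081
Rebaudioside C,beverage,0.052,0.175
Rebaudioside C,yogurt,0.016,0.053
Rebaudioside C,snack,0.017,0.058
Rebaudioside D,beverage,0.050,0.165
Rebaudioside D,yogurt,0.015,0.050
Rebaudioside D,snack,0.019,0.065
Rebaudioside F,beverage,0.056,0.187
Rebaudioside F,yogurt,0.022,0.075
Rebaudioside F,snack,0.021,0.069
Rubusoside,beverage,0.057,0.191
Rubusoside,yogurt,0.028,0.093
Rubusoside,snack,0.029,0.098
Dulcoside A,beverage,0.060,0.199
Dulcoside A,yogurt,0.018,0.061
Dulcoside A,snack,0.013,0.045
Stevioside,beverage,0.056,0.187
Stevioside,yogurt,0.023,0.078
Stevioside,snack,0.015,0.049
Steviolbioside,beverage,0.078,0.261
Steviolbioside,yogurt,0.020,0.066
Steviolbioside,snack,0.029,0.098
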