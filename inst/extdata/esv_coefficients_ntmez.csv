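service,forestland,grassland,cropland,water body,built-up land,unutilized land
gas regulation,4567.01,1043.89,652.43,0,0,0
climate regulation,3523.12,1174.37,1161.33,600.24,0,0
water conservation,4175.55,1043.89,782.92,26593.05,0,39.15
waste treatment,1709.37,1709.37,2139.97,23722.36,-9799.50,13.05
soil formation and protection,5088.95,2544.48,1905.10,13.05,-3209.96,26.10
biodiversity conservation,4253.84,1422.29,926.45,3249.10,0,443.65
food production,130.49,391.46,1304.86,130.49,0,13.05
raw material,3392.64,65.24,130.49,13.05,0,0
recreational culture,1670.22,52.19,13.049,5663.09,0,13.05
Total,28511.19,9447.19,9016.58,59984.41,-13009.45,548.04
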