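year,forestland,grassland,cropland,water body,built-up land,unutilized land
1980,3722.82,40938.98,10204.99,3093.59,643.15,37206.00
1990,3977.29,40888.34,9847.97,2956.23,812.80,36917.37
2000,4012.11,40428.76,10411.99,3272.74,994.48,36279.92
2010,3970.33,39461.50,11767.30,3392.38,1095.13,35713.36
2020,3851.32,38142.28,13732.84,3368.96,1540.78,34763.82
2030,3846.26,36252.00,13713.22,3357.56,1908.00,33390.00
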