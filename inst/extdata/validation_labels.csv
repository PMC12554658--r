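plant_id,truth,predicted
XinluzaoNo40_1,cylinder,cylinder
XinluzaoNo40_2,tower,tower
XinluzaoNo42_1,cylinder,cylinder
XinluzaoNo42_2,cylinder,tower
XinluzaoNo44_1,tower,tower
XinluzaoNo44_2,cylinder,cylinder
XinluzaoNo45_1,tower,cylinder
XinluzaoNo45_2,tower,tower
XinluzaoNo46_1,cylinder,tower
XinluzaoNo46_2,tower,tower
XinluzaoNo47_1,tower,cylinder
XinluzaoNo47_2,tower,tower
XinluzaoNo48_1,cylinder,cylinder
XinluzaoNo48_2,tower,tower
XinluzaoNo49_1,tower,tower
XinluzaoNo49_2,cylinder,cylinder
XinluzaoNo50_1,cylinder,tower
XinluzaoNo50_2,cylinder,cylinder
XinluzaoNo52_1,cylinder,cylinder
XinluzaoNo52_2,cylinder,cylinder
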