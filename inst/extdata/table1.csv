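DateTime,GDD,Growth days,Soil moisture 10,Soil moisture 20,Soil moisture 30,LAI
2018/6/13,194,12,28.45,29.81,25.02,1.26
2018/6/14,212,13,26.88,28.45,24.39,1.40
2018/6/15,231,14,25.62,27.02,23.59,1.56
2018/6/16,245,15,24.65,25.59,22.93,1.74
2018/6/17,260,16,24.71,25.6,22.8,1.95
2018/6/18,278,17,24.15,24.89,22.41,2.18
2018/6/19,297,18,23.23,23.61,21.76,2.43
2018/6/20,318,19,22.15,22.11,21.01,2.71
2018/6/21,337,20,21.14,20.9,20.38,3.01
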