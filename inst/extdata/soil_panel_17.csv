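soil_id,location,ph,oc_g_per_kg,cec_cmol_per_kg,clay_pct,background_pb_mg_per_kg
1,"Qiyang, Hunan",4.9,9.00,10.85,42.91,28.74
2,"Beibei, Chongqing",5.74,10.14,21.34,24.96,38.46
3,"Shenyang, Liaoning",5.74,14.99,12.19,17.32,31.60
4,"Kunming, Yunnan",5.92,19.87,11.10,27.52,42.51
5,"Yingtan, Jiangxi",6.01,6.78,8.70,36.51,34.75
6,"Hefei, Anhui",6.25,11.62,19.08,16.84,30.17
7,"Hailun, Heilongjiang",6.27,20.70,28.59,19.33,44.79
8,"Gongzhuling, Jilin",6.82,19.05,31.11,30.18,44.73
9,"Changshu, Jiangsu",6.93,27.66,26.20,45.94,37.48
10,"Yangling, Shaanxi",7.90,9.56,22.37,26.01,37.40
11,"Zhengzhou, Henan",8.07,10.32,16.01,18.18,36.12
12,"Urumqi, Xinjiang",8.12,11.27,25.25,9.57,40.87
13,"Taigu, Shanxi",8.24,13.44,16.80,17.74,38.58
14,"Tianjin",8.29,12.77,24.67,7.59,39.75
15,"Zhangye, Gansu",8.37,11.18,11.23,6.66,36.86
16,"Dezhou, Shandong",8.65,6.87,13.09,17.11,36.02
17,"Baotou, Inner Mongolia",8.8,9.45,11.61,10.51,40.80
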