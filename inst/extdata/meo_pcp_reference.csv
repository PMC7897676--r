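acronym,name,mh_composition,phase,artifact,rt_min,rt_all,exact_m0,accurate_m0,dm_m0,exact_m1,accurate_m1,dm_m1,exact_m2,accurate_m2,dm_m2,exact_m3,accurate_m3,dm_m3,product_ions
3-MeO-PCP,3-MeO-PCP,C18H28NO,parent,FALSE,7.74,7.74,274.2165,274.2164,-0.36,275.2199,275.2198,-0.36,276.2233,276.2231,-0.72,277.2266,277.2266,0,189.1272;121.0647;95.0492;91.0543;86.0965;81.0700
M1a,O-demethyl-,C17H26NO,I,FALSE,6.42,6.42,260.2009,260.2008,-0.38,261.2042,261.2041,-0.38,262.2076,262.2074,-0.76,263.2110,263.2109,-0.38,175.1115;107.0491;95.0492;91.0542;86.0965;81.0700;79.0544
M1b,O-demethyl-piperidine-OH-,C17H26NO2,I,FALSE,5.49,5.49,276.1958,276.1956,-0.72,277.1992,277.1990,-0.72,278.2025,278.2023,-0.72,279.2059,279.2061,0.72,175.1113;107.0490;102.0912;95.0491;84.0808;81.0699;77.0388
M1c,O-demethyl-cyclohexyl-HO-,C17H26NO2,I,FALSE,5.01,4.55;5.01;5.09,276.1958,276.1958,0,277.1992,277.1992,0,278.2025,278.2025,0,279.2059,279.2057,-0.72,173.0959;107.0491;86.0966;79.0544;77.0387
M1d,O-demethyl-cyclohexyl-HO-dehydro-oxo-piperidine-,C17H22NO3,I,FALSE,5.30,5.30,288.1594,288.1592,-0.69,289.1628,289.1625,-1.04,290.1661,290.1653,-2.76,NA,NA,NA,98.0601
M1e,Piperidine-HO-,C18H28NO2,I,FALSE,6.68,6.68,290.2115,290.2112,-1.03,291.2148,291.2146,-0.69,292.2182,292.2180,-0.68,293.2215,293.2211,-1.36,189.1274;121.0648;102.0914;91.0543;84.0809;81.0701
M1f,Cyclohexyl-HO- isomers,C18H28NO2,I,FALSE,5.62,5.62;6.18;6.34,290.2115,290.2112,-1.03,291.2148,291.2146,-0.69,292.2182,292.2179,-1.03,293.2215,293.2211,-1.36,205.1221;187.1116;121.0647;91.0543;86.0965;79.0544;77.0387
M1g,O-demethyl-piperidine-di-HO-,C17H26NO3,I,FALSE,5.88,5.88,292.1907,292.1903,-1.37,293.1941,293.1938,-1.02,294.1974,294.1971,-1.02,295.1983,295.1977,-2.03,175.1114;118.0860;107.0490;101.0597;81.0699;79.0544;77.0387
M1h,Piperidine-di-HO-,C18H28NO3,I,FALSE,6.95,6.95,306.2064,306.2061,-0.98,307.2097,307.2094,-0.98,308.2131,308.2129,-0.65,309.2140,309.2136,-1.29,189.1270;121.0646;118.0861;101.0597;100.0757;91.0543;81.0700
M1i,Cyclohexyl-HO-piperidine-HO- isomers,C18H28NO3,I,FALSE,4.45,4.45;5.15;5.33,306.2064,306.2063,-0.33,307.2097,307.2096,-0.33,308.2131,308.2131,0,309.2140,309.2127,-4.20,187.1114;121.0647;102.0914;84.0808
M1k,O-demethyl-cyclohexyl-HO-piperidine-di-HO-,C17H26NO4,I,FALSE,4.72,4.72,308.1856,308.1856,0,309.1890,309.1889,-0.32,310.1923,310.1921,-0.64,NA,NA,NA,191.1064;173.0958;118.0861;101.0597
M1m,Carboxy- methyl artifact,C19H30NO3,I,TRUE,7.86,7.86,320.2220,320.2217,-0.94,321.2254,321.2251,-0.93,322.2287,322.2285,-0.62,323.2296,323.2297,0.31,189.1271;132.1017;115.0753
M1n,O-(demethyl-carboxy-cyclohexyl-HO-) methyl artifact,C18H28NO4,I,TRUE,5.73,5.73,322.2013,322.2010,-0.93,323.2046,323.2044,-0.62,324.2080,324.2075,-1.54,NA,NA,NA,
M1o,Cyclohexyl-OH-piperidine-di-OH-,C18H28NO4,I,FALSE,5.04,5.04,322.2013,322.2012,-0.31,323.2046,323.2045,-0.31,324.2080,324.2081,0.31,325.2089,325.2079,-3.07,187.1115;118.0860;100.0756
M1p,Carboxy-cyclohexyl-HO- methyl artifact isomers,C19H30NO4,I,TRUE,7.69,7.52;7.69;8.23,336.2169,336.2166,-0.89,337.2203,337.2199,-1.19,338.2236,338.2230,-1.77,NA,NA,NA,
M2a,O-demethyl- glucuronide,C23H34NO7,II,FALSE,4.47,4.47,436.2330,436.2326,-0.92,437.2363,437.2359,-0.91,438.2397,438.2398,0.23,439.2406,439.2398,-1.82,175.1114;107.0490;95.0128;86.0964;81.0700;79.0544
M2b,O-demethyl-aryl-OH glucuronide,C23H34NO8,II,FALSE,3.41,3.41,452.2279,452.2274,-1.11,453.2312,453.2310,-0.44,454.2346,454.2346,0,455.2355,455.2344,-2.42,191.1063;173.0958;107.0490;86.0964;79.0543
M2c,O-demethyl-piperidine-OH- glucuronide,C23H34NO8,II,FALSE,4.07,4.07,452.2279,452.2275,-0.88,453.2312,453.2310,-0.44,454.2346,454.2346,0,455.2355,455.2346,-1.98,175.1114;107.0490;102.0913;84.0808;81.0699
M2d,O-demethyl-aryl-OH-dihydropyridine-OH- glucuronide,C23H30NO9,II,FALSE,4.20,4.20,464.1915,464.1914,-0.22,465.1949,465.1947,-0.43,466.1982,466.1982,0,467.1991,467.1987,-0.86,173.0958;98.0601;79.0545
M2e,Piperidine-OH glucuronide,C24H36NO8,II,FALSE,5.54,5.54,466.2435,466.2429,-1.29,467.2469,467.2465,-0.86,468.2503,468.2501,-0.43,469.2511,469.2501,-2.13,278.1227;189.1270;121.0646;102.0913;85.0284;84.0808;81.0700
M2f,O-demethyl-cyclohexyl-HO-piperidine-HO- glucuronide,C23H34NO9,II,FALSE,3.77,3.77,468.2228,468.2226,-0.43,469.2262,469.2258,-0.85,470.2295,470.2294,-0.21,471.2304,471.2298,-1.27,
M2g,O-demethyl-piperidine-di-OH- glucuronide,C23H34NO9,II,FALSE,4.44,4.44,468.2228,468.2225,-0.64,469.2262,469.2259,-0.64,470.2295,470.2293,-0.43,471.2304,471.2295,-1.91,145.0657;107.0490;84.0808;79.0543
M2h,Cyclohexyl-HO-piperidine-HO- glucuronide,C24H36NO9,II,FALSE,4.53,4.53,482.2385,482.2382,-0.62,483.2418,483.2416,-0.41,484.2452,484.2449,-0.62,485.2461,485.2465,0.82,187.1115;159.0802;121.0647;102.0914;84.0809
M2i,Piperidine-di-OH- glucuronide,C24H36NO9,II,FALSE,5.93,5.93,482.2385,482.2379,-1.24,483.2418,483.2414,-0.83,484.2452,484.2449,-0.62,485.2461,485.2460,-0.21,121.0646;118.0861
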