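"species","lignin_mg","val_cal_ratio","RPD","R2p","RMSEP_pct","SEP_pct"
17,144,0.58,,0.86,,1
1,519,0.59,3.96,0.94,1.33,1.39
2,1017,0.86,3.33,0.91,2.07,
5,566,0.23,1.34,0.47,,1.49
2,323,0.3,2.55,0.86,,
4,253,0.19,,0.05,,
2,214,0.36,0.9,0.05,0.67,0.73
1,437,0.57,1.88,0.73,,0.57
1,556,0.9,,0.6,1.18,1.22
1,,0.52,1.93,0.78,,1.78
2,547,0.71,2.44,0.83,,0.74
1,369,0.38,3.14,,,0.54
1,262,0.58,,0.88,1.76,1.59
31,134,0.63,,0.87,,
2,147,0.57,2.81,,0.98,0.93
2,430,0.68,2.64,0.82,,0.87
1,376,0.84,,,1.17,
1,336,0.65,4,0.95,2.53,
1,158,0.17,,0.92,,
1,225,,2.54,0.85,1.38,
1,525,0.58,2.43,0.81,,0.6
1,549,0.6,,0.83,1.5,1.47
14,296,0.46,2.55,0.85,,
2,186,0.28,,0.6,1.28,
2,294,0.87,2.51,0.91,0.92,
1,100,0.55,2.87,,,
1,507,0.31,1.64,0.65,1.02,0.93
3,134,0.72,1.97,,,0.68
1,,0.78,2.62,0.88,1.9,1.76
1,344,0.84,4.16,0.9,1.46,
1,164,,,0.68,1.92,2.04
1,668,0.33,1.72,0.73,0.6,
1,1546,0.54,2.06,0.7,0.73,0.71
2,233,0.58,2.65,0.85,,0.8
1,177,0.48,2.89,0.86,,
1,239,,3.08,0.88,,
2,1191,0.72,1.98,0.71,1.26,1.23
3,392,0.6,2.25,0.79,,
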