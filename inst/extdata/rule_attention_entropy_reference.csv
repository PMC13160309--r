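dataset,view,top5_pct,entropy,normalized_entropy,effective_rules,proportion_pct
Caltech7,1,13.12,3.9207,0.9972,50.44,98.9
Caltech7,2,12.90,3.9219,0.9975,50.5,99.01
Caltech7,3,16.15,3.8849,0.9881,48.66,95.42
Handwritten,1,15.461,3.8996,0.9918,49.38,96.83
Handwritten,2,12.698,3.9241,0.9980,50.61,99.23
Handwritten,3,22.041,3.8222,0.9721,45.71,89.62
Handwritten,4,12.692,3.9252,0.9983,50.66,99.34
Handwritten,5,9.881,3.9252,0.9983,50.66,99.34
Handwritten,6,14.561,3.8956,0.9908,49.18,96.44
Dermatology,1,13.958,3.9042,0.9930,49.61,97.28
Dermatology,2,12.145,3.9222,0.9976,50.51,99.05
Forest,1,16.792,3.8716,0.9847,48.02,94.15
Forest,2,14.059,3.9001,0.9919,49.41,96.88
EEG,1,12.845,3.9188,0.9967,50.34,98.71
EEG,2,16.132,3.8629,0.9825,47.61,93.34
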